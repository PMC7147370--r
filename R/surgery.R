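# Model surgery: enumerate the activation layers of a model graph and
# replace them, either uniformly with one chosen function or by independent
# stochastic draws from a pool.  Replacement never touches any other
# layer's weights.

# Run code with a private RNG stream, restoring the caller's stream after.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' List the replaceable activation slots of a model
#'
#' @param model A [model_graph()].
#' @return Integer vector of layer indices holding activation layers, in
#'   graph order (empty if the model has none).
#' @export
list_activation_slots <- function(model) {
  stopifnot(inherits(model, "model_graph"))
  which(vapply(model$layers, `[[`, "", "kind") == "act")
}

#' Replace every activation layer with one chosen function
#'
#' Each activation slot receives a freshly initialized instance of `spec`
#' (per-channel parameter shapes inferred from the slot's producing layer);
#' all other layers are untouched.  Because every learnable function in the
#' catalogue initializes to ReLU, replacing the activations of a ReLU
#' network with e.g. MeLU leaves the computed function unchanged until
#' training moves the coefficients.
#'
#' @param model A [model_graph()].
#' @param spec An [activation_spec()].
#' @param seed Integer seed for the APLU hinge-position draw (ignored by
#'   the other functions, whose initialization is deterministic).
#' @return The modified `model_graph`.
#' @export
replace_all <- function(model, spec, seed = 1L) {
  stopifnot(inherits(model, "model_graph"), inherits(spec, "activation_spec"))
  slots <- list_activation_slots(model)
  .with_seed(seed, {
    for (i in slots) {
      ch <- model$layers[[i]]$channels
      model$layers[[i]]$spec <- spec
      model$layers[[i]]$state <- activation_state(spec, ch)
    }
  })
  model
}

#' The default pool of nine alternative activation functions
#'
#' The nine non-ReLU members of the catalogue at a single `max_input`
#' value, the pool stochastic replacement draws from.  ReLU can be added
#' with `include_relu = TRUE`.
#'
#' @param max_input Normalization factor shared by the pool (1 or 255).
#' @param include_relu Also include plain ReLU (default `FALSE`).
#' @return List of [activation_spec()] objects.
#' @export
default_pool <- function(max_input = 1, include_relu = FALSE) {
  nms <- setdiff(activation_names(), if (!include_relu) "ReLU" else character())
  lapply(nms, activation_spec, max_input = max_input)
}

#' Stochastically replace all activation layers
#'
#' Each activation slot independently receives an activation drawn
#' uniformly (i.i.d., with replacement) from `pool`, freshly initialized
#' for the slot's channel count.  A master `seed` spawns one child seed per
#' slot; the draw and the state initialization of a slot consume only its
#' child stream, and the pool is put in a canonical order (by name, then
#' `max_input`) before drawing, so the assignment is a pure function of
#' `(model, pool, seed)` and stable under pool reordering.
#'
#' @param model A [model_graph()].
#' @param pool Non-empty list of [activation_spec()]s (see
#'   [default_pool()]).
#' @param seed Integer master seed.
#' @return List with `model` (the replaced graph) and `assignment`, a data
#'   frame with one row per slot: `slot_index`, `name`, `max_input`,
#'   `seed_used`.
#' @export
stochastic_replacement <- function(model, pool, seed) {
  stopifnot(inherits(model, "model_graph"))
  if (!length(pool)) stop("`pool` must be a non-empty list of activation specs")
  if (!all(vapply(pool, inherits, logical(1), "activation_spec")))
    stop("`pool` must contain activation_spec objects")
  ord <- order(vapply(pool, `[[`, "", "name"),
               vapply(pool, `[[`, 0, "max_input"))
  pool <- pool[ord]
  slots <- list_activation_slots(model)
  child <- .with_seed(seed,
    sample.int(.Machine$integer.max, length(slots)))
  rows <- vector("list", length(slots))
  for (s in seq_along(slots)) {
    i <- slots[[s]]
    .with_seed(child[s], {
      sp <- pool[[sample.int(length(pool), 1L)]]
      model$layers[[i]]$spec <- sp
      model$layers[[i]]$state <-
        activation_state(sp, model$layers[[i]]$channels)
    })
    sp <- model$layers[[i]]$spec
    rows[[s]] <- data.frame(slot_index = i, name = sp$name,
                            max_input = sp$max_input, seed_used = child[s])
  }
  list(model = model,
       assignment = if (length(rows)) do.call(rbind, rows)
                    else data.frame(slot_index = integer(), name = character(),
                                    max_input = numeric(), seed_used = integer()))
}
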