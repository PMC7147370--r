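# Ensemble construction and fusion.  Classification ensembles are fused by
# the sum rule: post-softmax score vectors are added across members and
# the decision is the argmax of the sum.  Segmentation ensembles sum
# per-pixel scores, which for hard one-hot masks reduces to a pixel-level
# majority vote.

#' Build an ensemble of stochastically replaced models
#'
#' Applies [stochastic_replacement()] to the base model `n` times with
#' distinct child seeds spawned from `seed`, optionally fine-tunes each
#' member with `trainer`, and collects the members and their assignment
#' manifests.
#'
#' @param base A [model_graph()].
#' @param pool Activation pool (see [default_pool()]).
#' @param n Number of members (>= 1).
#' @param seed Integer master seed.
#' @param trainer Optional `function(model, seed)` returning a trained
#'   model (e.g. a closure over [train_model()]); `NULL` keeps members at
#'   initialization.
#' @param recipe Label stored on the ensemble (`"FusRan"` by default).
#' @return An object of class `ensemble_model`: list with `members`,
#'   `manifests` (one assignment data frame per member) and `recipe`.
#' @export
create_ensemble <- function(base, pool, n, seed, trainer = NULL,
                            recipe = "FusRan") {
  stopifnot(inherits(base, "model_graph"))
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1")
  child <- .with_seed(seed, sample.int(.Machine$integer.max, n))
  members <- vector("list", n)
  manifests <- vector("list", n)
  for (i in seq_len(n)) {
    r <- stochastic_replacement(base, pool, child[i])
    m <- r$model
    if (!is.null(trainer)) m <- trainer(m, child[i])
    members[[i]] <- m
    manifests[[i]] <- r$assignment
  }
  structure(list(members = members, manifests = manifests, recipe = recipe),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("<ensemble_model>", x$recipe, "with", length(x$members), "members\n")
  invisible(x)
}

#' Fuse classification predictions by the sum rule
#'
#' Adds the members' post-softmax score matrices elementwise and takes the
#' argmax of the sum as the decision.  Fusion is permutation-invariant in
#' its arguments and invariant to scaling all inputs by a common positive
#' constant; argmax ties resolve to the lowest class index.
#'
#' @param predictions List of `N x K` score matrices (or of lists with a
#'   `scores` element, as returned by [predict_classes()]), all the same
#'   shape.
#' @return List with `scores` (the summed `N x K` matrix) and `decision`
#'   (integer labels in `1..K`).
#' @export
fuse_sum <- function(predictions) {
  scores <- lapply(predictions, function(p) if (is.list(p)) p$scores else p)
  if (!length(scores)) stop("`predictions` must be non-empty")
  d <- dim(scores[[1]])
  if (!all(vapply(scores, function(s) identical(dim(s), d), logical(1))))
    stop("all predictions must share the same shape")
  total <- Reduce(`+`, scores)
  list(scores = total, decision = max.col(total, ties.method = "first"))
}

#' Fuse segmentation masks by per-pixel score summation
#'
#' Sums the members' per-pixel class-score arrays and labels each pixel by
#' the argmax of the sum.  When members emit hard one-hot masks this equals
#' a per-pixel majority vote; ties resolve to the lowest class index.
#'
#' @param mask_scores List of `H x W x K` score arrays of identical shape.
#' @return Integer `H x W` label mask (labels in `1..K`).
#' @export
fuse_masks <- function(mask_scores) {
  if (!length(mask_scores)) stop("`mask_scores` must be non-empty")
  d <- dim(mask_scores[[1]])
  if (length(d) != 3L) stop("mask scores must be H x W x K arrays")
  if (!all(vapply(mask_scores, function(s) identical(dim(s), d), logical(1))))
    stop("all mask scores must share the same shape")
  total <- Reduce(`+`, mask_scores)
  lab <- matrix(1L, d[1], d[2])
  best <- total[, , 1L]
  for (k in seq_len(d[3])[-1]) {
    upd <- total[, , k] > best
    lab[upd] <- k
    best[upd] <- total[, , k][upd]
  }
  lab
}

#' Predict with an ensemble
#'
#' Runs every member and fuses with [fuse_sum()] (classification) or
#' [fuse_masks()] per image (segmentation).
#'
#' @param ensemble An `ensemble_model`.
#' @param x Image batch `H x W x C x N`.
#' @param mode `"classify"` or `"segment"`.
#' @return As [fuse_sum()] for classification; for segmentation, a list of
#'   fused label masks, one per image.
#' @export
predict_ensemble <- function(ensemble, x, mode = c("classify", "segment")) {
  stopifnot(inherits(ensemble, "ensemble_model"))
  mode <- match.arg(mode)
  if (mode == "classify") {
    fuse_sum(lapply(ensemble$members, function(m) predict_classes(m, x)$scores))
  } else {
    per_member <- lapply(ensemble$members, predict_masks, x = x)
    n_img <- length(per_member[[1]])
    lapply(seq_len(n_img), function(i)
      fuse_masks(lapply(per_member, `[[`, i)))
  }
}

#' Named ensemble recipes
#'
#' Thin constructors for the named ensembles: `FusRan<N>` fuses N
#' stochastically replaced models; `FusAct10` fuses the ten stand-alone
#' models obtained by uniform replacement with each catalogue function;
#' `FusAct3` fuses the wMeLU, MeLU and PReLU stand-alone models;
#' `FusRan20` is FusRan10 at `max_input = 1` plus FusRan10 at 255; and
#' `FusAR20` is FusAct10 plus FusRan10.
#'
#' @param recipe One of `"FusRan3"`, `"FusRan10"`, `"FusRan20"`,
#'   `"FusAct3"`, `"FusAct10"`, `"FusAR20"`.
#' @param base A [model_graph()] (a ReLU model to perturb).
#' @param seed Integer master seed.
#' @param trainer Optional `function(model, seed)`; see [create_ensemble()].
#' @param max_input Normalization factor for the pool / stand-alone specs
#'   (recipes ending in 20 combine 1 and 255 where noted).
#' @return An `ensemble_model`.
#' @export
ensemble_recipe <- function(recipe = c("FusRan3", "FusRan10", "FusRan20",
                                       "FusAct3", "FusAct10", "FusAR20"),
                            base, seed = 1L, trainer = NULL, max_input = 1) {
  recipe <- match.arg(recipe)
  ran <- function(n, mi, sd) create_ensemble(base, default_pool(mi), n, sd,
                                             trainer, recipe)
  act <- function(names, mi, sd) {
    members <- vector("list", length(names))
    manifests <- vector("list", length(names))
    child <- .with_seed(sd, sample.int(.Machine$integer.max, length(names)))
    for (i in seq_along(names)) {
      sp <- activation_spec(names[i], max_input = mi)
      m <- replace_all(base, sp, seed = child[i])
      if (!is.null(trainer)) m <- trainer(m, child[i])
      members[[i]] <- m
      manifests[[i]] <- data.frame(slot_index = list_activation_slots(base),
                                   name = names[i], max_input = mi,
                                   seed_used = child[i])
    }
    structure(list(members = members, manifests = manifests, recipe = recipe),
              class = "ensemble_model")
  }
  combine <- function(a, b) {
    structure(list(members = c(a$members, b$members),
                   manifests = c(a$manifests, b$manifests), recipe = recipe),
              class = "ensemble_model")
  }
  switch(recipe,
    FusRan3  = ran(3L, max_input, seed),
    FusRan10 = ran(10L, max_input, seed),
    FusRan20 = combine(ran(10L, 1, seed), ran(10L, 255, seed + 1L)),
    FusAct10 = act(activation_names(), max_input, seed),
    FusAct3  = act(c("wMeLU", "MeLU", "PReLU"), max_input, seed),
    FusAR20  = combine(act(activation_names(), max_input, seed),
                       ran(10L, max_input, seed + 1L))
  )
}

#' Select the best members by a reported metric
#'
#' A trivial sort: returns the indices of the `n` members with the highest
#' metric values (e.g. validation accuracy), for building lightweight
#' ensembles from a larger set.
#'
#' @param metrics Numeric vector, one value per member.
#' @param n How many members to keep.
#' @return Integer indices of the selected members.
#' @export
select_best <- function(metrics, n = 3L) {
  order(metrics, decreasing = TRUE)[seq_len(min(n, length(metrics)))]
}
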