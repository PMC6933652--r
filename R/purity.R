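#' Per-sample tumor purity
#'
#' A purity vector is a tibble with columns `sample_id` and `purity`, carrying
#' a `"scale"` attribute: `"original"` for values in `[0, 1]` (fractions of
#' cancer cells) or `"logit"` for their image on the real line. The boosted
#' regression is fit on the logit scale so predictions mapped back through the
#' inverse logit always land inside `(0, 1)`.
#'
#' @param sample_id character vector of sample IDs (unique).
#' @param purity numeric vector, same length.
#' @param scale `"original"` or `"logit"`.
#' @return A `purity_vec` tibble.
#' @export
purity_vector <- function(sample_id, purity, scale = c("original", "logit")) {
  scale <- match.arg(scale)
  sample_id <- as.character(sample_id)
  if (length(sample_id) != length(purity)) {
    stop("`sample_id` and `purity` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample IDs in purity vector", call. = FALSE)
  }
  if (any(!is.finite(purity))) stop("purity values must be finite", call. = FALSE)
  if (scale == "original" && (any(purity < 0) || any(purity > 1))) {
    stop("original-scale purity must lie in [0, 1]", call. = FALSE)
  }
  out <- tibble::tibble(sample_id = sample_id, purity = as.numeric(purity))
  class(out) <- c("purity_vec", class(out))
  attr(out, "scale") <- scale
  out
}

purity_scale <- function(p) attr(p, "scale")

#' Read / write a two-column purity TSV
#'
#' The file format is `sample_id<TAB>purity` with a header row.
#'
#' @param path file path.
#' @param scale scale of the stored values.
#' @return [load_purity()] returns a `purity_vec`; [write_purity()] returns
#'   `path` invisibly.
#' @export
load_purity <- function(path, scale = c("original", "logit")) {
  scale <- match.arg(scale)
  df <- readr::read_tsv(path, col_types = "cd", progress = FALSE,
                        show_col_types = FALSE)
  purity_vector(df[[1]], df[[2]], scale = scale)
}

#' @rdname load_purity
#' @param p a `purity_vec`.
#' @export
write_purity <- function(p, path) {
  readr::write_tsv(tibble::tibble(sample_id = p$sample_id, purity = p$purity),
                   path, progress = FALSE)
  invisible(path)
}

# Boundary constant: observed purities of exactly 1 are reassigned to 0.9975
# (and, symmetrically, 0 to 0.0025) so the logit is finite. Fixed, not
# recomputed from the data at hand.
PURITY_BOUNDARY <- 0.9975

#' Logit-transform purity values
#'
#' Values are first reassigned away from the boundaries (`1 -> 0.9975`,
#' `0 -> 0.0025`; anything in between is clamped into `[0.0025, 0.9975]`),
#' then mapped through `ln(v / (1 - v))`.
#'
#' @param p a `purity_vec` on the original scale.
#' @return A `purity_vec` on the logit scale.
#' @export
logit_transform <- function(p) {
  stopifnot(inherits(p, "purity_vec"))
  if (purity_scale(p) != "original") {
    stop("input purity is already on the logit scale", call. = FALSE)
  }
  v <- pmin(pmax(p$purity, 1 - PURITY_BOUNDARY), PURITY_BOUNDARY)
  purity_vector(p$sample_id, log(v / (1 - v)), scale = "logit")
}

#' Map logit-scale purity back to (0, 1)
#'
#' @param p a `purity_vec` on the logit scale.
#' @return A `purity_vec` on the original scale with values strictly inside
#'   `(0, 1)`.
#' @export
inverse_logit <- function(p) {
  stopifnot(inherits(p, "purity_vec"))
  if (purity_scale(p) != "logit") {
    stop("input purity is not on the logit scale", call. = FALSE)
  }
  purity_vector(p$sample_id, inv_logit_num(p$purity), scale = "original")
}

# numeric inverse logit; 1/(1+exp(-v)) stays < 1 in double precision for
# v <= ~36, and we clamp to just inside (0,1) beyond that
inv_logit_num <- function(v) {
  out <- 1 / (1 + exp(-v))
  eps <- .Machine$double.eps
  pmin(pmax(out, eps), 1 - eps)
}

logit_num <- function(v) {
  v <- pmin(pmax(v, 1 - PURITY_BOUNDARY), PURITY_BOUNDARY)
  log(v / (1 - v))
}

#' Split samples into a training and a test set
#'
#' Draws `round(fraction * n)` training samples uniformly at random
#' (deterministic given `seed`); the remainder form the test set.
#'
#' @param x an `expr_matrix`.
#' @param p a `purity_vec` aligned with `x` (same sample IDs).
#' @param fraction training fraction in (0, 1); default 2/3.
#' @param seed integer seed.
#' @return A `split_plan` list with `train_ids`, `test_ids`, `seed`,
#'   `train_fraction`.
#' @export
split_train_test <- function(x, p, fraction = 2 / 3, seed) {
  stopifnot(inherits(x, "expr_matrix"), inherits(p, "purity_vec"))
  ids <- sample_ids(x)
  if (!setequal(ids, p$sample_id)) {
    stop("expression matrix and purity vector must carry the same sample IDs",
         call. = FALSE)
  }
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1)", call. = FALSE)
  n <- length(ids)
  if (n < 2) stop("need at least 2 samples to split", call. = FALSE)
  n_train <- round(fraction * n)
  n_train <- min(max(n_train, 1), n - 1)
  old <- local_seed(seed)
  on.exit(old(), add = TRUE)
  train_ids <- sort(sample(ids, n_train))
  structure(
    list(train_ids = train_ids,
         test_ids = sort(setdiff(ids, train_ids)),
         seed = as.integer(seed),
         train_fraction = fraction),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d train / %d test (fraction %.3f, seed %d)\n",
              length(x$train_ids), length(x$test_ids), x$train_fraction, x$seed))
  invisible(x)
}

# Run code under a local RNG state: set the seed, and restore the caller's
# .Random.seed afterwards so library internals never perturb user RNG flow.
local_seed <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
}

# subset helpers used throughout the pipeline
subset_samples <- function(x, ids) {
  missing <- setdiff(ids, sample_ids(x))
  if (length(missing) > 0) {
    stop("unknown sample IDs: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  expr_matrix(x$values[ids, , drop = FALSE], scale = x$scale)
}

subset_purity <- function(p, ids) {
  idx <- match(ids, p$sample_id)
  if (anyNA(idx)) stop("unknown sample IDs in purity subset", call. = FALSE)
  purity_vector(ids, p$purity[idx], scale = purity_scale(p))
}

align_purity <- function(x, p) {
  if (!setequal(sample_ids(x), p$sample_id)) {
    stop("expression and purity sample IDs do not match", call. = FALSE)
  }
  subset_purity(p, sample_ids(x))
}
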