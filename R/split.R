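# Dataset splitting: deterministic, seed-driven partitions.

#' Split sample ids into train/validation/test
#'
#' Ids are shuffled with the given seed, then partitioned. Validation and
#' test sizes are the rounded fractions of the total; the remainder (largest
#' bucket) goes to train, so the three sizes always sum to the input size.
#'
#' @param ids character vector of sample ids (at least 3).
#' @param fractions numeric(3) `(train, validation, test)`, non-negative,
#'   summing to 1 within 1e-9.
#' @param seed integer seed; identical seeds give identical splits.
#' @return A [DatasetSplit-class].
#' @examples
#' sp <- splitDataset(sprintf("s%03d", 1:200), c(0.8, 0, 0.2), seed = 1)
#' lengths(list(sp@train, sp@validation, sp@test))  # 160, 0, 40
#' @export
splitDataset <- function(ids, fractions, seed) {
  ids <- as.character(ids)
  n <- length(ids)
  if (n < 3L) sizeError(sprintf("need at least 3 ids, got %d", n))
  if (length(fractions) != 3L || any(fractions < 0))
    configError("fractions must be 3 non-negative numbers")
  if (abs(sum(fractions) - 1) > 1e-9)
    configError(sprintf("fractions must sum to 1 (got %.12f)",
                        sum(fractions)))
  nVal <- round(fractions[2] * n)
  nTest <- round(fractions[3] * n)
  nTrain <- n - nVal - nTest
  if (nTrain < 0) configError("rounded validation+test exceed the id count")
  set.seed(as.integer(seed))
  perm <- sample(ids)
  new("DatasetSplit",
      train = perm[seq_len(nTrain)],
      validation = if (nVal > 0) perm[nTrain + seq_len(nVal)] else character(),
      test = if (nTest > 0) perm[nTrain + nVal + seq_len(nTest)] else character())
}

#' k-fold cross-validation splits
#'
#' Shuffles ids with the seed and deals them into `k` folds whose sizes
#' differ by at most one; each id lands in exactly one validation fold.
#'
#' @param ids character vector of sample ids.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return list of `k` lists, each `list(train = ..., validation = ...)`.
#' @examples
#' folds <- kfoldSplit(sprintf("s%02d", 1:10), k = 5, seed = 1)
#' lengths(lapply(folds, `[[`, "validation"))  # all 2
#' @export
kfoldSplit <- function(ids, k, seed) {
  ids <- as.character(ids)
  k <- as.integer(k)
  if (k < 2L) configError("k must be >= 2")
  if (k > length(ids))
    sizeError(sprintf("k = %d exceeds the number of ids (%d)", k,
                      length(ids)))
  set.seed(as.integer(seed))
  perm <- sample(ids)
  fold <- rep(seq_len(k), length.out = length(perm))
  lapply(seq_len(k), function(f)
    list(train = perm[fold != f], validation = perm[fold == f]))
}
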