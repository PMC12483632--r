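#' Stratified split specification
#'
#' Train/validation/test fractions, defaulting to the 70/15/15 protocol.
#' Fractions must be nonnegative and sum to 1 with a positive train
#' fraction; zero fractions are allowed for toy runs (e.g. `c(1, 0, 0)`).
#'
#' @param fractions numeric c(train, val, test).
#' @param seed integer seed for the per-class shuffles.
#' @return an object of class `SplitSpec`.
#' @export
splitSpec <- function(fractions = c(train = 0.70, val = 0.15, test = 0.15),
                      seed = 1) {
  stopifnot(length(fractions) == 3L, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-9, fractions[1] > 0)
  structure(list(fractions = setNames(as.numeric(fractions),
                                      c("train", "val", "test")),
                 seed = as.integer(seed)),
            class = "SplitSpec")
}

# Integer train allocation per class: floor of the per-class quota, then
# the remaining seats (up to the global round-half-up target) by largest
# remainder, ties broken by descending class size.
allocateTrain <- function(counts, fTrain) {
  target <- as.integer(roundHalfUp(fTrain * sum(counts), 0))
  quota <- fTrain * counts
  base <- pmin(floor(quota), counts)
  rem <- target - sum(base)
  # round remainders so exact-decimal ties are broken by class size,
  # not by floating-point noise
  ord <- order(-round(quota - base, 9), -counts)
  t <- base
  i <- 1L
  while (rem > 0L && i <= length(ord)) {
    k <- ord[i]
    if (t[k] < counts[k]) {
      t[k] <- t[k] + 1L
      rem <- rem - 1L
    }
    i <- i + 1L
  }
  while (rem < 0L) { # only reachable for extreme fractions
    k <- which.max(t)
    t[k] <- t[k] - 1L
    rem <- rem + 1L
  }
  t
}

#' Stratified train/validation/test split
#'
#' Partitions a bank into three disjoint, jointly exhaustive banks. The
#' global train count equals round-half-up(trainFraction * N); per-class
#' train allocation uses largest-remainder apportionment (ties broken by
#' descending class size), so each class's train share is within one record
#' of its exact quota. The per-class residual is divided between validation
#' and test proportionally to their fractions, an odd remainder going to
#' test. Assignment of individual records is by per-class shuffle,
#' deterministic given the spec seed.
#'
#' @param bank an [ImageBank-class]; every class needs at least as many
#'   records as there are splits with positive fraction.
#' @param spec a [splitSpec()].
#' @return named list of three `ImageBank`s: `train`, `val`, `test`.
#' @export
stratifiedSplit <- function(bank, spec = splitSpec()) {
  stopifnot(is(bank, "ImageBank"), inherits(spec, "SplitSpec"))
  f <- spec$fractions
  counts <- taxaCounts(bank)
  nPos <- sum(f > 0)
  short <- names(counts)[counts < nPos & counts > 0]
  if (length(short) > 0L) {
    stop("cannot populate all splits: class(es) with too few records: ",
         paste(short, collapse = ", "), call. = FALSE)
  }
  if (any(counts == 0L)) {
    stop("bank is missing class(es): ",
         paste(names(counts)[counts == 0L], collapse = ", "), call. = FALSE)
  }
  t <- allocateTrain(counts, f["train"])
  r <- counts - t
  # ensure val and test are populated per class when their fractions are
  # positive (guaranteed feasible since counts >= nPos)
  if (f["val"] > 0 && f["test"] > 0) {
    fix <- r < 2L
    t[fix] <- counts[fix] - 2L
    r <- counts - t
  } else if ((f["val"] > 0 || f["test"] > 0)) {
    fix <- r < 1L
    t[fix] <- counts[fix] - 1L
    r <- counts - t
  }
  if (f["val"] + f["test"] > 0) {
    v <- floor(r * f["val"] / (f["val"] + f["test"]))
    if (f["val"] > 0 && f["test"] > 0) v <- pmax(v, 1L)
  } else {
    v <- rep(0L, length(r))
  }
  te <- r - v
  idx <- classIndex(bank)
  pick <- list(train = integer(), val = integer(), test = integer())
  for (k in seq_along(taxonLevels())) {
    tx <- taxonLevels()[k]
    perm <- withr::with_seed(deriveSeed(spec$seed, paste0("split:", tx)),
                             sample(idx[[tx]]))
    pick$train <- c(pick$train, perm[seq_len(t[k])])
    if (v[k] > 0) pick$val <- c(pick$val, perm[t[k] + seq_len(v[k])])
    if (te[k] > 0) pick$test <- c(pick$test, perm[t[k] + v[k] + seq_len(te[k])])
  }
  lapply(pick, function(i) bank[sort(i)])
}

#' Write split assignments to CSV
#'
#' @param splits result of [stratifiedSplit()].
#' @param file output CSV path; columns `mark_id,taxon,split`.
#' @return the assignment data.frame, invisibly.
#' @export
writeSplit <- function(splits, file) {
  df <- do.call(rbind, lapply(names(splits), function(s) {
    rec <- bankRecords(splits[[s]])
    data.frame(mark_id = rec$mark_id, taxon = rec$taxon, split = s,
               stringsAsFactors = FALSE)
  }))
  write.csv(df, file, row.names = FALSE)
  invisible(df)
}
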