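#' Shot-task configuration
#'
#' The n-way k-shot structure of one training epoch: `nWay` classes (always
#' the full four-carnivore set here), `kShot` examples per class per
#' batch/episode, `nTasks` batches or episodes per epoch, and -- for the
#' meta-learning regime -- `qQuery` query examples per class per episode.
#'
#' @param kShot integer examples per class.
#' @param nTasks integer tasks per epoch.
#' @param qQuery integer query examples per class (meta-learning only;
#'   `NULL` for the supervised regime).
#' @param nWay integer number of classes (fixed at 4).
#' @return an object of class `ShotTaskConfig`.
#' @export
shotTaskConfig <- function(kShot, nTasks, qQuery = NULL, nWay = 4L) {
  assertCount(kShot, "kShot"); assertCount(nTasks, "nTasks")
  assertCount(nWay, "nWay")
  if (!is.null(qQuery)) assertCount(qQuery, "qQuery")
  structure(list(nWay = as.integer(nWay), kShot = as.integer(kShot),
                 nTasks = as.integer(nTasks),
                 qQuery = if (is.null(qQuery)) NULL else as.integer(qQuery)),
            class = "ShotTaskConfig")
}

#' Named shot-task presets
#'
#' The four tested configurations: `fssl-low` (5-shot, 40 tasks),
#' `fssl-high` (10-shot, 20 tasks), `maml-low` (5-shot, 40 tasks, 3 query
#' per class), `maml-high` (10-shot, 24 tasks, 3 query per class).
#'
#' @param name preset name.
#' @return a [shotTaskConfig()].
#' @export
shotTaskPreset <- function(name = c("fssl-low", "fssl-high",
                                    "maml-low", "maml-high")) {
  name <- match.arg(name)
  switch(name,
         "fssl-low" = shotTaskConfig(5L, 40L),
         "fssl-high" = shotTaskConfig(10L, 20L),
         "maml-low" = shotTaskConfig(5L, 40L, qQuery = 3L),
         "maml-high" = shotTaskConfig(10L, 24L, qQuery = 3L))
}

# Check that the bank holds every class the config asks for.
assertClassesPresent <- function(bank, config) {
  cnt <- taxaCounts(bank)
  absent <- names(cnt)[cnt == 0L]
  if (length(absent) > 0L) {
    stop("class(es) absent from bank: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  cnt
}

#' Sample the class-balanced batches of one supervised few-shot epoch
#'
#' Returns `nTasks` batches, each with exactly `kShot` records per class.
#' Within an epoch each class is sampled without replacement until
#' exhausted (a fresh shuffle of the class), after which sampling continues
#' with replacement; the policy is recorded per class in the
#' `replacementEngaged` attribute and the full draw log in the `drawLog`
#' attribute.
#'
#' @param bank an [ImageBank-class] containing all classes.
#' @param config a [shotTaskConfig()].
#' @param seed optional integer seed (`NULL`: current RNG stream).
#' @return list of `nTasks` data.frames (`mark_id`, `taxon`).
#' @export
sampleFewShotEpoch <- function(bank, config, seed = NULL) {
  stopifnot(inherits(config, "ShotTaskConfig"))
  assertClassesPresent(bank, config)
  run <- function() {
    rec <- bankRecords(bank)
    idx <- classIndex(bank)
    queues <- lapply(idx, sample)
    used <- setNames(rep(0L, length(idx)), names(idx))
    engaged <- setNames(rep(FALSE, length(idx)), names(idx))
    batches <- vector("list", config$nTasks)
    log <- list()
    for (task in seq_len(config$nTasks)) {
      pickRows <- integer()
      for (tx in taxonLevels()) {
        need <- config$kShot
        take <- integer()
        while (need > 0L) {
          avail <- length(queues[[tx]]) - used[[tx]]
          if (avail == 0L) {
            queues[[tx]] <- sample(idx[[tx]])
            used[[tx]] <- 0L
            engaged[[tx]] <- TRUE
            avail <- length(queues[[tx]])
          }
          m <- min(need, avail)
          take <- c(take, queues[[tx]][used[[tx]] + seq_len(m)])
          used[[tx]] <- used[[tx]] + m
          need <- need - m
        }
        pickRows <- c(pickRows, take)
      }
      batches[[task]] <- data.frame(mark_id = rec$mark_id[pickRows],
                                    taxon = rec$taxon[pickRows],
                                    path = rec$path[pickRows],
                                    stringsAsFactors = FALSE)
      log[[task]] <- data.frame(task_index = task, role = "batch",
                                mark_id = batches[[task]]$mark_id,
                                taxon = batches[[task]]$taxon,
                                stringsAsFactors = FALSE)
    }
    attr(batches, "replacementEngaged") <- engaged
    attr(batches, "drawLog") <- do.call(rbind, log)
    batches
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Sample one support/query episode
#'
#' Draws `kShot` support and `qQuery` query records per class. Support and
#' query are disjoint whenever the class holds at least `kShot + qQuery`
#' records; smaller classes fill the query with replacement from the whole
#' class. A class smaller than `kShot` is an error.
#'
#' @param bank an [ImageBank-class].
#' @param config a [shotTaskConfig()] with non-`NULL` `qQuery`.
#' @param seed optional integer seed.
#' @return an object of class `Episode`: list with data.frames `support`
#'   and `query` (`mark_id`, `taxon`).
#' @export
sampleEpisode <- function(bank, config, seed = NULL) {
  stopifnot(inherits(config, "ShotTaskConfig"), !is.null(config$qQuery))
  cnt <- assertClassesPresent(bank, config)
  small <- names(cnt)[cnt < config$kShot]
  if (length(small) > 0L) {
    stop("class(es) smaller than kShot = ", config$kShot, ": ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  run <- function() {
    rec <- bankRecords(bank)
    idx <- classIndex(bank)
    sup <- qry <- integer()
    for (tx in taxonLevels()) {
      perm <- sample(idx[[tx]])
      sup <- c(sup, perm[seq_len(config$kShot)])
      restN <- length(perm) - config$kShot
      if (restN >= config$qQuery) {
        qry <- c(qry, perm[config$kShot + seq_len(config$qQuery)])
      } else {
        pool <- if (restN > 0L) perm[-seq_len(config$kShot)] else idx[[tx]]
        qry <- c(qry, c(perm[config$kShot + seq_len(restN)],
                        sample(pool, config$qQuery - restN, replace = TRUE)))
      }
    }
    toDf <- function(i) data.frame(mark_id = rec$mark_id[i],
                                   taxon = rec$taxon[i],
                                   path = rec$path[i],
                                   stringsAsFactors = FALSE)
    structure(list(support = toDf(sup), query = toDf(qry)),
              class = "Episode")
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Tabulate batches or episodes for audit export
#'
#' @param x a list of batches from [sampleFewShotEpoch()] or a single
#'   episode from [sampleEpisode()].
#' @return data.frame with columns `task_index`, `role`, `mark_id`,
#'   `taxon`, suitable for CSV export.
#' @export
episodeTable <- function(x) {
  if (inherits(x, "Episode")) {
    cols <- c("mark_id", "taxon")
    rbind(cbind(task_index = 1L, role = "support", x$support[cols]),
          cbind(task_index = 1L, role = "query", x$query[cols]))
  } else {
    attr(x, "drawLog")
  }
}
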