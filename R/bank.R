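#' ImageBank: a labelled collection of tooth-mark images
#'
#' Container for a class-labelled image bank. Records are kept as a
#' data.frame with columns `mark_id`, `taxon`, `path`, `height`, `width`,
#' sorted by taxon then mark id, so enumeration is deterministic.
#'
#' @slot records data.frame of mark records.
#' @slot root character; bank root directory (may be `NA` for manifests).
#' @aliases ImageBank
#' @export
setClass("ImageBank",
         representation(records = "data.frame", root = "character"))

setValidity("ImageBank", function(object) {
  rec <- object@records
  need <- c("mark_id", "taxon", "path", "height", "width")
  if (!all(need %in% names(rec))) {
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  }
  bad <- setdiff(unique(rec$taxon), taxonLevels())
  if (length(bad) > 0L) return(paste("unknown taxon:", paste(bad, collapse = ", ")))
  if (anyDuplicated(rec$mark_id)) return("duplicate mark_id values")
  TRUE
})

# Internal constructor: sorts records canonically.
ImageBank <- function(records, root = NA_character_) {
  records <- records[order(records$taxon, records$mark_id), , drop = FALSE]
  rownames(records) <- NULL
  new("ImageBank", records = records, root = root)
}

#' @describeIn ImageBank-class number of records
#' @param x,object an `ImageBank`.
#' @export
setMethod("length", "ImageBank", function(x) nrow(x@records))

#' Bank record table
#' @param bank an [ImageBank-class].
#' @return data.frame of records.
#' @export
bankRecords <- function(bank) bank@records

#' Per-taxon record counts
#' @param bank an [ImageBank-class].
#' @return named integer vector over [taxonLevels()].
#' @export
taxaCounts <- function(bank) {
  tab <- table(factor(bank@records$taxon, levels = taxonLevels()))
  setNames(as.integer(tab), taxonLevels())
}

#' Record indices per taxon
#' @param bank an [ImageBank-class].
#' @return named list mapping each taxon to its record row indices.
#' @export
classIndex <- function(bank) {
  lapply(setNames(nm = taxonLevels()),
         function(tx) which(bank@records$taxon == tx))
}

#' @describeIn ImageBank-class subset by record index
#' @param i integer or logical index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "ImageBank", function(x, i, j, ..., drop = FALSE) {
  ImageBank(x@records[i, , drop = FALSE], root = x@root)
})

setMethod("show", "ImageBank", function(object) {
  cnt <- taxaCounts(object)
  cat(sprintf("ImageBank with %d records (%s)\n", length(object),
              paste(sprintf("%s: %d", names(cnt), cnt), collapse = ", ")))
})

#' Read one RGB image
#'
#' Reads a PNG or TIFF file into an (h x w x 3) array in [0, 1]. Grayscale
#' or alpha-bearing images are rejected: the bank contract is RGB.
#'
#' @param path file path.
#' @return RGB array.
#' @export
loadImage <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch({
    if (ext %in% c("tif", "tiff")) {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("the 'tiff' package is required to read TIFF images")
      }
      tiff::readTIFF(path)
    } else {
      png::readPNG(path)
    }
  }, error = function(e) {
    stop("cannot read image '", path, "': ", conditionMessage(e), call. = FALSE)
  })
  if (length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop("image '", path, "' is not a 3-channel RGB image", call. = FALSE)
  }
  img
}

#' Load an image bank
#'
#' Accepts either a directory with one subdirectory per taxon
#' (`<root>/<taxon>/<mark>.png`) or a manifest CSV with header
#' `mark_id,taxon,path,height,width` (paths resolved relative to the
#' manifest's directory). The two representations of the same bank
#' enumerate identical record sets.
#'
#' @param path bank root directory or manifest CSV path.
#' @return an [ImageBank-class].
#' @export
loadBank <- function(path) {
  if (dir.exists(path)) {
    sub <- list.dirs(path, full.names = FALSE, recursive = FALSE)
    sub <- setdiff(sub, "")
    bad <- setdiff(sub, taxonLevels())
    if (length(bad) > 0L) {
      stop("unknown taxon director", if (length(bad) > 1) "ies: " else "y: ",
           paste(bad, collapse = ", "),
           " (expected subset of: ", paste(taxonLevels(), collapse = ", "), ")",
           call. = FALSE)
    }
    rows <- list()
    for (tx in intersect(taxonLevels(), sub)) {
      files <- sort(list.files(file.path(path, tx),
                               pattern = "\\.(png|tif|tiff)$",
                               ignore.case = TRUE, full.names = TRUE))
      for (f in files) {
        img <- loadImage(f)
        markId <- tools::file_path_sans_ext(basename(f))
        rows[[paste(tx, markId)]] <- data.frame(
          mark_id = markId, taxon = tx, path = f,
          height = dim(img)[1], width = dim(img)[2],
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0L) {
      stop("no images found under ", path, call. = FALSE)
    }
    return(ImageBank(do.call(rbind, rows), root = path))
  }
  if (file.exists(path)) {
    rec <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("mark_id", "taxon", "path", "height", "width")
    if (!all(need %in% names(rec))) {
      stop("manifest must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (nrow(rec) == 0L) stop("manifest is empty: ", path, call. = FALSE)
    root <- dirname(normalizePath(path))
    abs <- file.path(root, rec$path)
    rec$path <- ifelse(file.exists(rec$path), rec$path, abs)
    missing <- !file.exists(rec$path)
    if (any(missing)) {
      stop("manifest image file(s) not found, e.g.: ", rec$path[which(missing)[1]],
           call. = FALSE)
    }
    return(ImageBank(rec, root = root))
  }
  stop("no such bank directory or manifest: ", path, call. = FALSE)
}
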