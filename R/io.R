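# Delimited-table I/O. One file per modality: header row of feature labels,
# first column of subject ids. Labels file: two columns (subject id, class).

.guess_sep <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a modality table from a delimited file
#'
#' The file must have a header row of feature labels and a first column of
#' subject ids; every other cell must be numeric. Row and column order are
#' preserved. Non-numeric or missing cells are reported with their subject
#' and feature.
#'
#' @param path Path to a CSV (or TSV, by extension) file.
#' @param modality Modality tag to attach.
#' @param sep Field separator; guessed from the extension by default.
#' @return A [feature_matrix()].
#' @export
read_modality_matrix <- function(path, modality = "modality1", sep = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(sep)) sep <- .guess_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (ncol(tab) < 3L) {
    stop(sprintf("malformed table '%s': need an id column plus >= 2 features",
                 path), call. = FALSE)
  }
  ids <- tab[[1L]]
  labs <- colnames(tab)[-1L]
  vals <- matrix(NA_real_, nrow(tab), length(labs))
  for (j in seq_along(labs)) {
    col <- suppressWarnings(as.numeric(tab[[j + 1L]]))
    bad <- which(is.na(col))
    if (length(bad) > 0L) {
      stop(sprintf(
        "non-numeric or missing cell in '%s' at subject '%s' (row %d), feature '%s': '%s'",
        path, ids[bad[1L]], bad[1L], labs[j], tab[[j + 1L]][bad[1L]]
      ), call. = FALSE)
    }
    vals[, j] <- col
  }
  feature_matrix(vals, ids, labs, modality)
}

#' Write a modality table to a delimited file
#'
#' Inverse of [read_modality_matrix()]: header row of feature labels, first
#' column (`subject_id`) of subject ids, full double precision.
#'
#' @param fm A [feature_matrix()].
#' @param path Output path (CSV unless the extension says TSV).
#' @param sep Field separator; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_modality_matrix <- function(fm, path, sep = NULL) {
  stopifnot(inherits(fm, "fc2fs_feature_matrix"))
  if (is.null(sep)) sep <- .guess_sep(path)
  df <- data.frame(subject_id = fm$subject_ids,
                   as.data.frame(fm$values), check.names = FALSE)
  colnames(df) <- c("subject_id", fm$feature_labels)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a subject labels file
#'
#' Expects two columns: subject id and class name. The positive (+1) class is
#' by convention the disease group; by default it is the second distinct class
#' in file order.
#'
#' @param path Path to the labels file.
#' @param positive_class Name of the class to code +1; default second distinct
#'   class encountered.
#' @param sep Field separator; guessed from the extension by default.
#' @return List with `labels` (a [label_vector()]) and `subject_ids`.
#' @export
read_labels <- function(path, positive_class = NULL, sep = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(sep)) sep <- .guess_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("labels file needs two columns: id, class",
                           call. = FALSE)
  cls <- tab[[2L]]
  lev <- unique(cls)
  if (length(lev) != 2L) {
    stop(sprintf("labels file must contain exactly 2 classes, found %d",
                 length(lev)), call. = FALSE)
  }
  if (is.null(positive_class)) positive_class <- lev[2L]
  if (!positive_class %in% lev) {
    stop(sprintf("positive class '%s' not present in labels file",
                 positive_class), call. = FALSE)
  }
  y <- ifelse(cls == positive_class, 1L, -1L)
  list(labels = label_vector(y, positive_class_name = positive_class),
       subject_ids = tab[[1L]])
}

#' Write a labels file
#'
#' @param labels A [label_vector()].
#' @param subject_ids Subject identifiers, same order as the labels.
#' @param path Output path.
#' @param negative_class Name used for the -1 class.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, subject_ids, path,
                         negative_class = "control") {
  stopifnot(inherits(labels, "fc2fs_labels"))
  df <- data.frame(subject_id = subject_ids,
                   class = ifelse(labels$values > 0,
                                  labels$positive_class_name, negative_class))
  utils::write.table(df, path, sep = .guess_sep(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ROI name map
#'
#' Two columns: feature label, anatomical region name (e.g. AAL names for
#' region reports).
#'
#' @param path Path to the mapping file.
#' @param sep Field separator; guessed from the extension by default.
#' @return Named character vector mapping feature label to region name.
#' @export
read_roi_map <- function(path, sep = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(sep)) sep <- .guess_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("ROI map needs two columns: feature label, name",
                           call. = FALSE)
  stats::setNames(tab[[2L]], tab[[1L]])
}
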