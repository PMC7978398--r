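#' Assemble a labeled PPG dataset
#'
#' A dataset bundles segments that share one sampling geometry with their
#' quality labels and, for artifactual records, the expert annotation
#' intervals and the per-sample masks derived from them. The explainability
#' metrics consume the `(attention, mask)` pairs of the annotated records.
#'
#' @param x Numeric matrix, one row per record, `n` columns of samples.
#' @param fs Sampling rate in Hz shared by all records.
#' @param record_id Character vector of unique record identifiers.
#' @param label Character vector of quality labels
#'   (`"ARTIFACT_FREE"`/`"ARTIFACTUAL"`/`"UNLABELED"`).
#' @param intervals Named list of [annotation_intervals()] (or `NULL` entries),
#'   keyed by record id; records absent from the list carry no annotation.
#' @return An object of class `ppg_dataset`.
#' @export
ppg_dataset <- function(x, fs, record_id = rownames(x),
                        label = rep("UNLABELED", nrow(x)),
                        intervals = list()) {
  x <- as.matrix(x)
  if (is.null(record_id)) record_id <- sprintf("rec%04d", seq_len(nrow(x)))
  record_id <- as.character(record_id)
  if (anyDuplicated(record_id)) stop("record ids must be unique")
  if (length(record_id) != nrow(x) || length(label) != nrow(x))
    stop("record_id/label lengths must match the number of rows")
  bad <- setdiff(names(intervals), record_id)
  if (length(bad)) stop("annotations reference unknown record ids: ",
                        paste(bad, collapse = ", "))
  if (!all(label %in% c("ARTIFACT_FREE", "ARTIFACTUAL", "UNLABELED")))
    stop("unknown quality label")
  n <- ncol(x)
  mask <- vector("list", nrow(x)); names(mask) <- record_id
  for (id in names(intervals)) {
    if (!is.null(intervals[[id]]))
      mask[[id]] <- intervals_to_mask(intervals[[id]], fs = fs, n = n)
  }
  structure(list(x = x, fs = fs, record_id = record_id, label = label,
                 intervals = intervals, mask = mask),
            class = "ppg_dataset")
}

#' @export
print.ppg_dataset <- function(x, ...) {
  n_ann <- sum(!vapply(x$mask, is.null, logical(1)))
  cat(sprintf("<ppg_dataset: %d records x %d samples @ %g Hz>\n",
              nrow(x$x), ncol(x$x), x$fs))
  cat(sprintf("  labels: %s\n",
              paste(sprintf("%s=%d", names(table(x$label)), table(x$label)),
                    collapse = ", ")))
  cat(sprintf("  annotated records: %d\n", n_ann))
  invisible(x)
}

#' @export
`[.ppg_dataset` <- function(x, i, ...) {
  ids <- x$record_id[i]
  ppg_dataset(x$x[i, , drop = FALSE], fs = x$fs, record_id = ids,
              label = x$label[i],
              intervals = x$intervals[intersect(names(x$intervals), ids)])
}

#' @export
length.ppg_dataset <- function(x) nrow(x$x)

#' Indices of the annotated (artifactual) records of a dataset
#'
#' The explainability metrics are defined only on records carrying an
#' annotation mask; this helper returns their row indices.
#'
#' @param dataset A [ppg_dataset()].
#' @return Integer vector of row indices.
#' @export
annotated_records <- function(dataset) {
  which(!vapply(dataset$mask, is.null, logical(1)))
}

#' Read a dataset from signal and annotation tables
#'
#' Signals are a CSV with a `record_id` column followed by one column per
#' sample; annotations are a BED-like half-open interval table in seconds
#' with header `record_id,onset_s,offset_s`, one row per interval. Masks are
#' materialized from the intervals at read time. A record that appears in the
#' annotation table is labeled `ARTIFACTUAL`, any other record
#' `ARTIFACT_FREE` (override with a `label` column in the signal table).
#'
#' @param signals_path Path to the signals CSV.
#' @param annotations_path Optional path to the annotations CSV.
#' @param fs Sampling rate in Hz declared for the files.
#' @return A [ppg_dataset()].
#' @export
read_ppg_dataset <- function(signals_path, annotations_path = NULL, fs = 240) {
  sig <- utils::read.csv(signals_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!"record_id" %in% names(sig)) stop("signals file lacks a record_id column")
  ids <- as.character(sig$record_id)
  label_col <- NULL
  if ("label" %in% names(sig)) {
    label_col <- as.character(sig$label)
    sig$label <- NULL
  }
  x <- as.matrix(sig[setdiff(names(sig), "record_id")])
  if (anyNA(x) || !is.numeric(x))
    stop("signal rows must be complete numeric vectors of equal length")
  storage.mode(x) <- "double"
  intervals <- list()
  if (!is.null(annotations_path)) {
    ann <- utils::read.csv(annotations_path, stringsAsFactors = FALSE)
    need <- c("record_id", "onset_s", "offset_s")
    if (!all(need %in% names(ann)))
      stop("annotations file needs columns record_id, onset_s, offset_s")
    bad <- setdiff(unique(ann$record_id), ids)
    if (length(bad)) stop("annotations reference unknown record ids: ",
                          paste(bad, collapse = ", "))
    dur <- (ncol(x) - 1) / fs
    for (id in unique(ann$record_id)) {
      rows <- ann[ann$record_id == id, ]
      intervals[[id]] <- annotation_intervals(rows$onset_s, rows$offset_s,
                                              duration_s = dur, record_id = id)
    }
  }
  label <- if (!is.null(label_col)) label_col else
    ifelse(ids %in% names(intervals), "ARTIFACTUAL", "ARTIFACT_FREE")
  ppg_dataset(x, fs = fs, record_id = ids, label = label, intervals = intervals)
}

#' Write a dataset to signal and annotation tables
#'
#' Inverse of [read_ppg_dataset()]: the same CSV conventions are used, so a
#' written dataset reads back identically (up to numeric formatting).
#'
#' @param dataset A [ppg_dataset()].
#' @param signals_path,annotations_path Output CSV paths; annotations are
#'   skipped when `annotations_path` is `NULL`.
#' @return Invisibly, the dataset.
#' @export
write_ppg_dataset <- function(dataset, signals_path, annotations_path = NULL) {
  df <- data.frame(record_id = dataset$record_id, label = dataset$label,
                   dataset$x, check.names = FALSE)
  names(df) <- c("record_id", "label", sprintf("s%d", seq_len(ncol(dataset$x))))
  utils::write.csv(df, signals_path, row.names = FALSE)
  if (!is.null(annotations_path)) {
    rows <- do.call(rbind, lapply(names(dataset$intervals), function(id) {
      iv <- dataset$intervals[[id]]
      if (is.null(iv) || !nrow(iv)) return(NULL)
      data.frame(record_id = id, onset_s = iv$onset_s, offset_s = iv$offset_s)
    }))
    if (is.null(rows))
      rows <- data.frame(record_id = character(), onset_s = numeric(),
                         offset_s = numeric())
    utils::write.csv(rows, annotations_path, row.names = FALSE)
  }
  invisible(dataset)
}

#' Write attention maps to a CSV table
#'
#' One row per record: `record_id`, the saliency `method` tag, then one
#' column per sample.
#'
#' @param maps Named list of nonnegative numeric vectors (one per record).
#' @param path Output CSV path.
#' @param method Saliency method tag recorded with every map.
#' @return Invisibly, `maps`.
#' @export
write_attention_maps <- function(maps, path, method = "unknown") {
  stopifnot(length(maps) > 0)
  m <- do.call(rbind, maps)
  df <- data.frame(record_id = names(maps), method = method, m,
                   check.names = FALSE)
  names(df) <- c("record_id", "method", sprintf("s%d", seq_len(ncol(m))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(maps)
}

#' Read attention maps written by [write_attention_maps()]
#'
#' @param path CSV path.
#' @return Named list of numeric vectors with attribute `method`.
#' @export
read_attention_maps <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[setdiff(names(df), c("record_id", "method"))])
  maps <- lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
  names(maps) <- df$record_id
  attr(maps, "method") <- unique(df$method)
  maps
}
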