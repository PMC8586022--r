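#' Kmer model container
#'
#' A kmer model maps each kmer to its characteristic ionic-current level
#' (mean, pA; optionally a standard deviation). Stored as a data.frame with
#' columns `kmer`, `level_mean` and optionally `level_stdv`, plus
#' `nucleic_type` and `provenance` attributes.
#'
#' @param x Data frame with columns `kmer`, `level_mean`
#'   (and optionally `level_stdv`).
#' @param nucleic_type `"DNA"` or `"RNA"`.
#' @param provenance Free-text provenance tag.
#' @return A `kmer_model` data.frame.
#' @export
kmer_model <- function(x, nucleic_type = c("DNA", "RNA"),
                       provenance = "unknown") {
  nucleic_type <- match.arg(nucleic_type)
  if (!all(c("kmer", "level_mean") %in% names(x)))
    stop("a kmer model needs 'kmer' and 'level_mean' columns")
  if (anyDuplicated(x$kmer))
    stop("duplicate kmer(s): ",
         paste(utils::head(x$kmer[duplicated(x$kmer)], 5), collapse = ", "))
  if (!all(is.finite(x$level_mean)))
    stop("non-finite level_mean values")
  ks <- nchar(gsub("\\[[^]]*\\]", "x", x$kmer))
  if (length(unique(ks)) > 1)
    stop("mixed kmer lengths: ", paste(unique(ks), collapse = ", "))
  structure(as.data.frame(x), class = c("kmer_model", "data.frame"),
            nucleic_type = nucleic_type, provenance = provenance,
            k = if (nrow(x) > 0) as.integer(ks[1]) else NA_integer_)
}

#' Read a kmer-model table
#'
#' Parses tab-separated kmer-model tables. Header and `#`-comment lines are
#' tolerated. The `ont` dialect expects columns `kmer` and `level_mean`
#' (extra columns such as `level_stdv` are kept); the `nanopolish` dialect
#' additionally maps the modified-base letter `M` to `5mC`.
#'
#' @param path File path.
#' @param dialect `"ont"` or `"nanopolish"`.
#' @param nucleic_type `"DNA"` or `"RNA"`.
#' @return A [kmer_model()].
#' @examples
#' read_kmer_model(system.file("extdata", "example_kmer_model.tsv",
#'                             package = "kmergcn"))
#' @export
read_kmer_model <- function(path, dialect = c("ont", "nanopolish"),
                            nucleic_type = c("DNA", "RNA")) {
  dialect <- match.arg(dialect)
  nucleic_type <- match.arg(nucleic_type)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) stop("empty kmer model file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) > 1)
    stop("ragged kmer model table at line ",
         which(nf != nf[1])[1], " of ", path)
  header <- fields[[1]]
  has_header <- "kmer" %in% header
  cols <- if (has_header) header else c("kmer", "level_mean", "level_stdv")[seq_len(nf[1])]
  body <- if (has_header) fields[-1] else fields
  if (length(body) == 0)
    return(kmer_model(data.frame(kmer = character(0), level_mean = numeric(0)),
                      nucleic_type, provenance = path))
  tab <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
  names(tab) <- cols
  if (!all(c("kmer", "level_mean") %in% names(tab)))
    stop("kmer model table lacks 'kmer'/'level_mean' columns: ", path)
  num_cols <- intersect(c("level_mean", "level_stdv"), names(tab))
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    if (anyNA(v))
      stop("non-numeric ", cn, " at line ",
           which(is.na(v))[1] + has_header, " of ", path)
    tab[[cn]] <- v
  }
  if (dialect == "nanopolish")
    tab$kmer <- gsub("M", "[5mC]", tab$kmer, fixed = TRUE)
  kmer_model(tab[, c("kmer", num_cols)], nucleic_type, provenance = path)
}

#' Write a kmer-model table
#'
#' Writes a tab-separated model with a header line, kmers sorted
#' lexicographically, and fixed 5-decimal formatting, so output is
#' byte-identical across runs.
#'
#' @param model A [kmer_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kmer_model <- function(model, path) {
  stopifnot(inherits(model, "kmer_model"))
  num_cols <- intersect(c("level_mean", "level_stdv"), names(model))
  out <- model[order(model$kmer), c("kmer", num_cols), drop = FALSE]
  lines <- c(paste(c("kmer", num_cols), collapse = "\t"))
  if (nrow(out) > 0) {
    vals <- vapply(num_cols, function(cn) sprintf("%.5f", out[[cn]]),
                   character(nrow(out)))
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
    lines <- c(lines, paste(out$kmer, apply(vals, 1, paste, collapse = "\t"),
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

.EVENTALIGN_REQUIRED <- c("contig", "position", "reference_kmer", "read_index",
                          "strand", "event_index", "event_level_mean",
                          "event_stdv", "event_length", "model_kmer",
                          "model_mean", "model_stdv")

#' Read a nanopolish eventalign event table
#'
#' Parses the tab-separated per-read event table produced by
#' `nanopolish eventalign --scale-events`. Columns are matched by name, so
#' permuted column orders are fine. Rows whose `model_kmer` is the all-`N`
#' placeholder (events that could not be assigned a kmer) are skipped and
#' counted. Reference positions are 0-based, following the upstream tool.
#'
#' @param path File path.
#' @return A data.frame of event records, with attribute `n_skipped` giving
#'   the number of placeholder rows dropped.
#' @examples
#' ev <- read_eventalign(system.file("extdata", "example_eventalign.tsv",
#'                                   package = "kmergcn"))
#' attr(ev, "n_skipped")  # one NNNNN placeholder row
#' @export
read_eventalign <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE, showProgress = FALSE)
  missing_cols <- setdiff(.EVENTALIGN_REQUIRED, names(tab))
  if (length(missing_cols) > 0)
    stop("eventalign table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  for (cn in c("event_level_mean", "event_stdv", "event_length")) {
    if (!is.numeric(tab[[cn]])) {
      v <- suppressWarnings(as.numeric(tab[[cn]]))
      if (anyNA(v))
        stop("malformed numeric field '", cn, "' at line ",
             which(is.na(v))[1] + 1L, " of ", path)
      tab[[cn]] <- v
    }
  }
  if (!all(is.finite(tab$event_level_mean)))
    stop("non-finite event_level_mean values in ", path)
  placeholder <- grepl("^N+$", tab$model_kmer)
  out <- tab[!placeholder, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(placeholder)
  out
}

#' Build an empirical kmer model from event tables
#'
#' For every `model_kmer`, averages the `event_level_mean` of all its event
#' instances (arithmetic mean). Kmers observed fewer than `min_count` times
#' are excluded and reported in the `excluded` attribute. Accepts a
#' data.frame of events, a file path, or a vector of file paths; multiple
#' tables are accumulated in a streaming fashion (per-kmer running sums), so
#' the result is independent of row order and chunking.
#'
#' @param events Event data.frame from [read_eventalign()], or path(s).
#' @param min_count Minimum number of instances per kmer (default 1: average
#'   all recorded instances).
#' @param nucleic_type `"DNA"` or `"RNA"`.
#' @return A [kmer_model()] with a `counts` attribute (instances per kept
#'   kmer) and an `excluded` attribute.
#' @export
empirical_model_from_events <- function(events, min_count = 1L,
                                        nucleic_type = c("DNA", "RNA")) {
  nucleic_type <- match.arg(nucleic_type)
  chunks <- if (is.character(events)) lapply(events, read_eventalign)
            else list(events)
  sums <- numeric(0)
  counts <- numeric(0)
  for (ch in chunks) {
    s <- tapply(ch$event_level_mean, ch$model_kmer, sum)
    n <- tapply(ch$event_level_mean, ch$model_kmer, length)
    all_k <- union(names(sums), names(s))
    new_sums <- structure(numeric(length(all_k)), names = all_k)
    new_counts <- new_sums
    new_sums[names(sums)] <- sums
    new_counts[names(counts)] <- counts
    new_sums[names(s)] <- new_sums[names(s)] + s
    new_counts[names(n)] <- new_counts[names(n)] + n
    sums <- new_sums; counts <- new_counts
  }
  if (length(sums) == 0) {
    warning("no events to average; empty model")
    return(kmer_model(data.frame(kmer = character(0), level_mean = numeric(0)),
                      nucleic_type, provenance = "eventalign"))
  }
  keep <- counts >= min_count
  if (!any(keep)) warning("all kmers below min_count; empty model")
  ord <- order(names(sums)[keep])
  mdl <- kmer_model(
    data.frame(kmer = names(sums)[keep][ord],
               level_mean = (sums[keep] / counts[keep])[ord],
               stringsAsFactors = FALSE),
    nucleic_type, provenance = "eventalign")
  attr(mdl, "counts") <- unname(counts[keep][ord])
  attr(mdl, "excluded") <- names(sums)[!keep]
  mdl
}

#' Look up model values for a kmer set
#'
#' @param model A [kmer_model()].
#' @param kmers Character vector of kmers; all must be present.
#' @return Named numeric vector of level means (pA).
#' @export
model_levels <- function(model, kmers) {
  idx <- match(kmers, model$kmer)
  if (anyNA(idx))
    stop("kmer(s) missing from model: ",
         paste(utils::head(kmers[is.na(idx)], 5), collapse = ", "))
  structure(model$level_mean[idx], names = kmers)
}
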