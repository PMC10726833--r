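#' Filtering configuration for scored interaction records
#'
#' Bundles the two reliability rules applied to raw interaction data before any
#' network is built: a confidence cutoff for probability-like scores in
#' \eqn{[0,1]}, and a per-publication overflow rule for scoring systems whose
#' values exceed 1 (keep only records scoring strictly more than
#' `overflow_multiplier` times the publication's mean score).
#'
#' @param confidence_threshold Minimum score kept for publications whose scores
#'   all lie in \eqn{[0,1]}. Records with `score >= confidence_threshold`
#'   survive ("below threshold" is removed, so the threshold itself survives).
#' @param overflow_multiplier Multiplier on the per-publication mean for
#'   publications containing any score greater than 1; records must score
#'   strictly above `overflow_multiplier * mean` to survive.
#' @param drop_genetic Drop records whose experimental system type is not
#'   `"physical"` (genetic and unknown types are removed and counted).
#' @param drop_self_loops Drop self-interactions when merging into a unique
#'   pair set.
#' @return An object of class `filter_config`.
#' @examples
#' filter_config()
#' @export
filter_config <- function(confidence_threshold = 0.85,
                          overflow_multiplier = 1.5,
                          drop_genetic = TRUE,
                          drop_self_loops = TRUE) {
  stopifnot(
    is.numeric(confidence_threshold), length(confidence_threshold) == 1L,
    confidence_threshold >= 0, confidence_threshold <= 1,
    is.numeric(overflow_multiplier), length(overflow_multiplier) == 1L,
    overflow_multiplier > 0
  )
  structure(
    list(
      confidence_threshold = confidence_threshold,
      overflow_multiplier = overflow_multiplier,
      drop_genetic = isTRUE(drop_genetic),
      drop_self_loops = isTRUE(drop_self_loops)
    ),
    class = "filter_config"
  )
}

# Canonical empty record table; keeps column types stable for rbind.
empty_records <- function() {
  data.frame(
    protein_a = character(0), protein_b = character(0),
    system_type = character(0), score = numeric(0),
    publication_id = character(0), source = character(0),
    self_interaction = logical(0),
    stringsAsFactors = FALSE
  )
}

clean_symbol <- function(x) toupper(trimws(as.character(x)))

normalize_system_type <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x == "physical"] <- "physical"
  out[x == "genetic"] <- "genetic"
  out
}

make_records <- function(protein_a, protein_b, system_type, score,
                         publication_id, source) {
  protein_a <- clean_symbol(protein_a)
  protein_b <- clean_symbol(protein_b)
  df <- data.frame(
    protein_a = protein_a,
    protein_b = protein_b,
    system_type = normalize_system_type(system_type),
    score = as.numeric(score),
    publication_id = as.character(publication_id),
    source = as.character(source),
    self_interaction = protein_a == protein_b,
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  df
}

#' Read scored interaction records from a tab-separated file
#'
#' Parses BioGRID-TAB-like or STRING-like edge lists into a uniform record
#' table. Gene symbols are uppercased and whitespace-trimmed; no identifier
#' mapping is attempted. Malformed rows (missing symbols, unparseable scores,
#' negative scores) are counted and returned in a report attached to the
#' result, never silently dropped.
#'
#' Dialects:
#' \describe{
#'   \item{`generic_tsv`}{Header row with columns `protein_a`, `protein_b`,
#'     `system_type`, `score`, `publication_id`, `source` (the last is
#'     optional).}
#'   \item{`biogrid_tab`}{Headerless, positional: symbol A, symbol B,
#'     experimental system type, score, publication identifier, and an optional
#'     source label (defaults to `"biogrid"`).}
#'   \item{`string_edges`}{Headerless: protein A, protein B, combined score on
#'     the 0--1000 scale, rescaled to \eqn{[0,1]}; system type is `physical`,
#'     publication id and source are `"string"`.}
#' }
#'
#' @param path Path to a TSV file.
#' @param dialect One of `"generic_tsv"`, `"biogrid_tab"`, `"string_edges"`.
#' @return A data frame of interaction records (columns `protein_a`,
#'   `protein_b`, `system_type`, `score`, `publication_id`, `source`,
#'   `self_interaction`) with attribute `report`: a list with `rows_read`,
#'   `n_malformed` and the malformed raw rows.
#' @seealso [filter_interactions()] for the downstream reliability filter.
#' @export
read_interactions <- function(path,
                              dialect = c("generic_tsv", "biogrid_tab",
                                          "string_edges")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)

  header <- dialect == "generic_tsv"
  raw <- utils::read.delim(path, header = header, sep = "\t",
                           colClasses = "character", comment.char = "#",
                           stringsAsFactors = FALSE, quote = "")
  if (nrow(raw) == 0L) {
    out <- empty_records()
    attr(out, "report") <- list(rows_read = 0L, n_malformed = 0L,
                                malformed = raw[0, , drop = FALSE])
    return(out)
  }

  if (dialect == "generic_tsv") {
    mandatory <- c("protein_a", "protein_b", "system_type", "score",
                   "publication_id")
    missing_cols <- setdiff(mandatory, names(raw))
    if (length(missing_cols) > 0L) {
      stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
    }
    if (!"source" %in% names(raw)) raw$source <- "generic"
    fields <- raw[, c(mandatory, "source")]
  } else if (dialect == "biogrid_tab") {
    if (ncol(raw) < 5L) stop("missing mandatory column: biogrid_tab needs ",
                             "5 columns (A, B, system type, score, publication)")
    if (ncol(raw) < 6L) raw[[6L]] <- "biogrid"
    fields <- raw[, 1:6]
    names(fields) <- c("protein_a", "protein_b", "system_type", "score",
                       "publication_id", "source")
  } else { # string_edges
    if (ncol(raw) < 3L) stop("missing mandatory column: string_edges needs ",
                             "3 columns (A, B, combined score)")
    fields <- data.frame(
      protein_a = raw[[1L]], protein_b = raw[[2L]],
      system_type = "physical", score = raw[[3L]],
      publication_id = "string", source = "string",
      stringsAsFactors = FALSE
    )
  }

  score_num <- suppressWarnings(as.numeric(fields$score))
  if (dialect == "string_edges") score_num <- score_num / 1000
  bad <- is.na(score_num) | score_num < 0 |
    !nzchar(trimws(fields$protein_a)) | !nzchar(trimws(fields$protein_b))

  records <- make_records(fields$protein_a[!bad], fields$protein_b[!bad],
                          fields$system_type[!bad], score_num[!bad],
                          fields$publication_id[!bad], fields$source[!bad])
  attr(records, "report") <- list(
    rows_read = nrow(raw),
    n_malformed = sum(bad),
    malformed = raw[bad, , drop = FALSE]
  )
  records
}

#' Keep only physical interactions
#'
#' Genetic interactions, and records whose system type could not be
#' recognized, are removed; only records typed `physical` survive. Input order
#' is preserved. The number of dropped records is attached as attribute
#' `n_dropped`.
#'
#' @param records Interaction record data frame (see [read_interactions()]).
#' @return The surviving records, with attribute `n_dropped`.
#' @export
filter_physical <- function(records) {
  keep <- records$system_type == "physical"
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

# Publication groups containing any score > 1 use a different scoring system
# and are handled by the overflow rule, not the probability-like cutoff.
overflow_publications <- function(records) {
  if (nrow(records) == 0L) return(character(0))
  mx <- tapply(records$score, records$publication_id, max)
  names(mx)[mx > 1]
}

#' Confidence cutoff for probability-like scores
#'
#' For records whose publication's scores all lie in \eqn{[0,1]}, keep only
#' those with `score >= confidence_threshold` ("below the threshold" is
#' removed, so a score exactly at the threshold survives). Records belonging to
#' publications with any score above 1 pass through untouched; they are the
#' province of [filter_overflow_scores()].
#'
#' @param records Interaction record data frame.
#' @param config A [filter_config()].
#' @return The surviving records, order preserved.
#' @export
filter_by_confidence <- function(records, config = filter_config()) {
  if (nrow(records) == 0L) return(records)
  overflow <- records$publication_id %in% overflow_publications(records)
  keep <- overflow | records$score >= config$confidence_threshold
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-publication overflow-score selection
#'
#' For each publication whose score multiset contains any value greater than 1
#' (a non-probability scoring system), the arithmetic mean of that
#' publication's scores is computed and only records scoring strictly above
#' `overflow_multiplier` times that mean are kept. Publications entirely within
#' \eqn{[0,1]} pass through untouched. A consequence of the strict inequality
#' is that a single-record publication with score above 1 is always dropped
#' (its mean equals its score).
#'
#' @inheritParams filter_by_confidence
#' @return The surviving records, order preserved.
#' @export
filter_overflow_scores <- function(records, config = filter_config()) {
  if (nrow(records) == 0L) return(records)
  over_pubs <- overflow_publications(records)
  overflow <- records$publication_id %in% over_pubs
  keep <- !overflow
  if (any(overflow)) {
    means <- tapply(records$score[overflow],
                    records$publication_id[overflow], mean)
    thresh <- config$overflow_multiplier * means[records$publication_id[overflow]]
    keep[overflow] <- records$score[overflow] > thresh
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge record sets into a canonical unique pair set
#'
#' Deduplicates undirected protein pairs across sources and orientations:
#' \code{A--B} and \code{B--A} collapse to one pair with endpoints sorted
#' lexicographically. Self-interactions are removed when the configuration says
#' so. For each unique pair the maximum score and the sorted union of source
#' labels are retained.
#'
#' @param ... One or more interaction record data frames.
#' @param config A [filter_config()]; only `drop_self_loops` is consulted.
#' @return A data frame with columns `protein_a`, `protein_b` (sorted within
#'   each row and across rows), `score` (max across duplicates) and `sources`
#'   (comma-separated label union).
#' @export
merge_unique <- function(..., config = filter_config()) {
  sets <- list(...)
  sets <- sets[vapply(sets, function(x) nrow(x) > 0L, logical(1))]
  if (length(sets) == 0L) {
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      score = numeric(0), sources = character(0),
                      stringsAsFactors = FALSE))
  }
  rec <- do.call(rbind, lapply(sets, function(x) {
    x[, c("protein_a", "protein_b", "score", "source")]
  }))
  if (config$drop_self_loops) rec <- rec[rec$protein_a != rec$protein_b, ,
                                         drop = FALSE]
  a <- pmin(rec$protein_a, rec$protein_b)
  b <- pmax(rec$protein_a, rec$protein_b)
  key <- paste(a, b, sep = "\t")
  score <- tapply(rec$score, key, max)
  src <- tapply(rec$source, key, function(s)
    paste(sort(unique(s)), collapse = ","))
  keys <- sort(unique(key))
  parts <- strsplit(keys, "\t", fixed = TRUE)
  out <- data.frame(
    protein_a = vapply(parts, `[`, character(1), 1L),
    protein_b = vapply(parts, `[`, character(1), 2L),
    score = as.numeric(score[keys]),
    sources = as.character(src[keys]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Apply the full reliability filter and merge to a unique pair set
#'
#' Pipeline order: physical-only filter, overflow-score rule, confidence
#' cutoff, then merge to canonical unique pairs. The overflow and confidence
#' rules act on disjoint publication strata (publications with any score above
#' 1 versus publications entirely within \eqn{[0,1]}), so their relative order
#' does not change the result.
#'
#' @param ... One or more interaction record data frames.
#' @param config A [filter_config()].
#' @return A canonical pair data frame (see [merge_unique()]) with attribute
#'   `report`: per-rule drop counts usable in a run report.
#' @export
filter_interactions <- function(..., config = filter_config()) {
  sets <- list(...)
  report <- list(rows_in = sum(vapply(sets, nrow, integer(1))))
  if (config$drop_genetic) {
    sets <- lapply(sets, filter_physical)
    report$dropped_non_physical <- report$rows_in -
      sum(vapply(sets, nrow, integer(1)))
  } else {
    report$dropped_non_physical <- 0L
  }
  n0 <- sum(vapply(sets, nrow, integer(1)))
  sets <- lapply(sets, filter_overflow_scores, config = config)
  n1 <- sum(vapply(sets, nrow, integer(1)))
  report$dropped_overflow_rule <- n0 - n1
  sets <- lapply(sets, filter_by_confidence, config = config)
  n2 <- sum(vapply(sets, nrow, integer(1)))
  report$dropped_low_confidence <- n1 - n2
  pairs <- do.call(merge_unique, c(sets, list(config = config)))
  report$unique_pairs <- nrow(pairs)
  attr(pairs, "report") <- report
  pairs
}

#' Write a canonical edge list and a JSON filter report
#'
#' @param pairs Output of [filter_interactions()] or [merge_unique()].
#' @param path Output TSV path (two sorted symbol columns, max score, sources).
#' @param report_path Optional JSON path for the filter report attached to
#'   `pairs`.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(pairs, path, report_path = NULL) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(report_path)) {
    rep <- attr(pairs, "report")
    if (is.null(rep)) rep <- list(unique_pairs = nrow(pairs))
    jsonlite::write_json(rep, report_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
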