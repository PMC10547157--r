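#' Filter phosphoketolase hit tables
#'
#' Applies the mining filters to a blastp-style best-hit table: keep records
#' whose best-hit class matches the target AND whose percent identity is
#' strictly greater than 40 AND whose alignment length is strictly greater
#' than 600 residues. Boundary strictness is literal ("more than"): records
#' at exactly 40 or 600 are dropped. The filter is order-preserving and
#' idempotent. Upstream hmmscan/blastp/clustering runs are consumed as
#' pre-computed tables, not re-run.
#'
#' @param records Tibble with columns `query`, `class` (best-hit class
#'   label), `identity` (percent, 0--100), `length` (aligned residues).
#' @param target_class Best-hit class to retain (e.g. `"XFP"`).
#' @param min_identity,min_length Strict lower bounds (defaults 40 and 600).
#' @return The retained rows, original order.
#' @examples
#' hits <- tibble::tibble(query = c("a", "b"), class = c("XFP", "XFP"),
#'                        identity = c(41, 40), length = c(601, 700))
#' filter_hits(hits, "XFP")  # keeps only "a"
#' @export
filter_hits <- function(records, target_class, min_identity = 40,
                        min_length = 600) {
  stopifnot(all(c("query", "class", "identity", "length") %in% names(records)))
  if (any(records$identity < 0 | records$identity > 100)) {
    stop("identity must be in [0, 100]", call. = FALSE)
  }
  dplyr::filter(records,
                .data$class == target_class,
                .data$identity > min_identity,
                .data$length > min_length)
}

as_alignment_matrix <- function(alignment) {
  if (inherits(alignment, "AAStringSet") || inherits(alignment, "BStringSet")) {
    alignment <- stats::setNames(as.character(alignment), names(alignment))
  }
  if (is.matrix(alignment)) return(alignment)
  stopifnot(is.character(alignment))
  if (length(alignment) == 0) stop("empty alignment", call. = FALSE)
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1) {
    stop("ragged alignment: rows differ in length", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(alignment, ""))
  rownames(m) <- names(alignment) %||% paste0("seq", seq_along(alignment))
  m
}

#' Column-wise majority consensus of an alignment
#'
#' Per column, the most frequent residue; gaps (`-`) are excluded from the
#' tally unless a column is entirely gaps (then the consensus is a gap).
#' Ties resolve to the alphabetically first residue (the source procedure is
#' silent on ties; the rule is fixed so results are reproducible).
#'
#' @param alignment Named character vector of equal-length aligned sequences,
#'   a character matrix (rows = sequences), or a `Biostrings` string set.
#' @return Single consensus string.
#' @examples
#' consensus_of(c(a = "ACD", b = "ACD", c = "AQD"))  # "ACD"
#' @export
consensus_of <- function(alignment) {
  m <- as_alignment_matrix(alignment)
  cons <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col <- col[col != "-"]
    if (length(col) == 0) return("-")
    tab <- table(col)
    # which.max on a table breaks ties by names order = alphabetical
    names(tab)[which.max(tab)]
  }, character(1))
  paste(cons, collapse = "")
}

#' Consensus-closest representative of a sequence family
#'
#' Builds the column-wise majority consensus and selects the member sequence
#' with the maximum count of positions matching it -- the "closest
#' approximation to the supposed optimal sequence" used to pick one
#' representative per ortholog group. Positions where either the sequence or
#' the consensus carries a gap are excluded from the match count. Ties break
#' deterministically by input order and are recorded. An alternative metric,
#' `"identity"`, scores the fraction of compared (both non-gap) positions
#' instead of the raw match count.
#'
#' @inheritParams consensus_of
#' @param metric `"matches"` (default: raw count of consensus-matching
#'   columns) or `"identity"` (matches / compared columns).
#' @return Object of class `consensus_result`: list with `consensus`,
#'   `representative` (name), `index`, `tie` (logical), and `scores` (tibble
#'   with per-sequence `matches`, `compared`, `identity`).
#' @examples
#' fam <- gen_protein_family(30, 8, 0.1, seed = 2)
#' closest_to_consensus(fam)
#' @export
closest_to_consensus <- function(alignment, metric = c("matches", "identity")) {
  metric <- match.arg(metric)
  m <- as_alignment_matrix(alignment)
  cons <- strsplit(consensus_of(m), "")[[1]]
  cmp <- t(m) == cons & t(m) != "-" & cons != "-"
  compared <- colSums(t(m) != "-" & cons != "-")
  matches <- colSums(cmp)
  identity <- ifelse(compared > 0, matches / compared, 0)
  score <- if (metric == "matches") matches else identity
  idx <- which.max(score)  # first max = input-order tie-break
  structure(list(
    consensus = paste(cons, collapse = ""),
    representative = rownames(m)[idx],
    index = unname(idx),
    tie = sum(score == max(score)) > 1,
    metric = metric,
    scores = tibble::tibble(
      id = rownames(m),
      matches = as.integer(unname(matches)),
      compared = as.integer(unname(compared)),
      identity = unname(identity)
    )
  ), class = "consensus_result")
}

#' Read or write an aligned FASTA file
#'
#' Thin wrappers over `Biostrings` returning/accepting the named character
#' vectors that [consensus_of()] and [closest_to_consensus()] consume.
#'
#' @param path FASTA file path.
#' @param sequences Named character vector of sequences.
#' @return `read_alignment()`: named character vector; `write_alignment()`:
#'   `path` invisibly.
#' @export
read_alignment <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required to read FASTA alignments", call. = FALSE)
  }
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_alignment
#' @export
write_alignment <- function(sequences, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required to write FASTA alignments", call. = FALSE)
  }
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(unclass(sequences)), path)
  invisible(path)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus-closest representative\n")
  cat("  representative: ", x$representative,
      if (x$tie) "  (tie, first by input order)" else "", "\n", sep = "")
  cat("  metric: ", x$metric, "\n", sep = "")
  cat("  consensus (", nchar(x$consensus), " columns): ",
      substr(x$consensus, 1, 60),
      if (nchar(x$consensus) > 60) "..." else "", "\n", sep = "")
  invisible(x)
}
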