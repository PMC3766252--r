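#' Field comparison configuration
#'
#' Fields are compared by exact equality after canonicalization (trim
#' whitespace, case-fold); values equal to one of the `na_tokens` (after
#' canonicalization) count as missing, and any comparison involving a
#' missing value is coded as a disagreement.
#'
#' @param fields Character vector of unique field names to compare.
#' @param na_tokens Values treated as missing markers.
#' @return An object of class `lc_field_config`.
#' @export
field_config <- function(fields, na_tokens = c("", "NA", "NULL")) {
  fields <- as.character(fields)
  if (length(fields) == 0L) stopf("field list must be non-empty")
  if (anyDuplicated(fields)) stopf("field names must be unique")
  structure(list(fields = fields, na_tokens = tolower(trimws(as.character(na_tokens)))),
            class = "lc_field_config")
}

# canonical form used for all equality tests; NA for missing markers
canonicalize <- function(x, na_tokens) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | x %in% na_tokens] <- NA_character_
  x
}

#' Binary agreement vector for one record pair
#'
#' Component `k` is 1 iff both values of the k-th configured field are
#' non-missing and canonically equal; missing values are coded as
#' disagreements.
#'
#' @param record_a,record_b Named lists or named character vectors exposing
#'   every configured field.
#' @param config A [field_config()] (or a character vector of field names).
#' @return Integer 0/1 vector named by field.
#' @export
compare_records <- function(record_a, record_b, config) {
  if (!inherits(config, "lc_field_config")) config <- field_config(config)
  for (f in config$fields) {
    if (!f %in% names(record_a)) stopf("field '%s' missing from first record", f)
    if (!f %in% names(record_b)) stopf("field '%s' missing from second record", f)
  }
  a <- canonicalize(unlist(record_a[config$fields]), config$na_tokens)
  b <- canonicalize(unlist(record_b[config$fields]), config$na_tokens)
  agree <- !is.na(a) & !is.na(b) & a == b
  stats::setNames(as.integer(agree), config$fields)
}

#' Candidate record pairs agreeing on blocking fields
#'
#' Restricts the pair search space to pairs whose blocking-field values are
#' all non-missing and canonically equal. In de-duplication mode (one record
#' set) only pairs `i < j` are produced; with a second record set the
#' within-block cross product is produced.
#'
#' @param records A data.frame of records.
#' @param blocking_fields Character vector of blocking field names.
#' @param records2 Optional second data.frame for two-file linkage.
#' @param na_tokens Missing-value markers (see [field_config()]).
#' @return A two-column integer matrix of row indices (columns `i`, `j`).
#' @export
block_pairs <- function(records, blocking_fields, records2 = NULL,
                        na_tokens = c("", "NA", "NULL")) {
  cfg <- field_config(blocking_fields, na_tokens)
  key_of <- function(df) {
    for (f in blocking_fields)
      if (!f %in% names(df)) stopf("blocking field '%s' missing from records", f)
    cols <- lapply(df[blocking_fields], canonicalize, na_tokens = cfg$na_tokens)
    ok <- !Reduce(`|`, lapply(cols, is.na))
    key <- do.call(paste, c(cols, sep = "\r"))
    key[!ok] <- NA_character_
    key
  }
  empty <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j")))
  key1 <- key_of(records)
  if (is.null(records2)) {
    groups <- split(seq_along(key1)[!is.na(key1)], key1[!is.na(key1)])
    pairs <- lapply(groups, function(idx) {
      if (length(idx) < 2L) return(NULL)
      t(utils::combn(sort(idx), 2L))
    })
    pairs <- do.call(rbind, pairs)
  } else {
    key2 <- key_of(records2)
    g1 <- split(seq_along(key1)[!is.na(key1)], key1[!is.na(key1)])
    g2 <- split(seq_along(key2)[!is.na(key2)], key2[!is.na(key2)])
    shared <- intersect(names(g1), names(g2))
    pairs <- do.call(rbind, lapply(shared, function(k)
      as.matrix(expand.grid(i = g1[[k]], j = g2[[k]], KEEP.OUT.ATTRS = FALSE))))
  }
  if (is.null(pairs) || nrow(pairs) == 0L) return(empty)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  dimnames(pairs) <- list(NULL, c("i", "j"))
  storage.mode(pairs) <- "integer"
  pairs
}

#' Agreement-pattern frequency table
#'
#' The sufficient statistic of the linkage model: counts `f_d` over all
#' `D = 2^K` binary agreement patterns in the fixed [pattern_matrix()]
#' order. Unobserved patterns carry count 0.
#'
#' @param counts Numeric vector of `2^K` non-negative counts.
#' @param field_names Character vector of `K` field labels.
#' @return An object of class `lc_agreement_table` with elements `K`,
#'   `patterns`, `counts`, `N`, `field_names`.
#' @export
agreement_table <- function(counts, field_names) {
  K <- length(field_names)
  D <- 2L^K
  counts <- unname(as.numeric(counts))
  if (length(counts) != D) stopf("counts must have length 2^K = %d", D)
  if (any(counts < 0) || any(!is.finite(counts))) stopf("counts must be non-negative")
  if (anyDuplicated(field_names)) stopf("field names must be unique")
  structure(list(K = K, patterns = pattern_matrix(K), counts = counts,
                 N = sum(counts), field_names = as.character(field_names)),
            class = "lc_agreement_table")
}

#' @export
print.lc_agreement_table <- function(x, ...) {
  cat(sprintf("Agreement pattern table: K = %d fields (%s), N = %s pairs, %d/%d patterns observed\n",
              x$K, paste(x$field_names, collapse = ", "),
              format(x$N, big.mark = ",", scientific = FALSE), sum(x$counts > 0), length(x$counts)))
  invisible(x)
}

#' Tabulate binary agreement vectors into a pattern table
#'
#' @param vectors A matrix with one 0/1 agreement vector per row (or a list
#'   of such vectors), each of length `K`.
#' @param K Number of fields; defaults to the vector length.
#' @param field_names Optional `K` field labels.
#' @return An [agreement_table()].
#' @export
build_pattern_table <- function(vectors, K = NULL, field_names = NULL) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  if (is.null(vectors) || length(vectors) == 0L) {
    if (is.null(K)) stopf("K required for an empty vector stream")
    vectors <- matrix(integer(0), ncol = K)
  }
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1L)
  if (is.null(K)) K <- ncol(vectors)
  if (ncol(vectors) != K) stopf("agreement vectors have length %d, expected K=%d",
                                ncol(vectors), K)
  if (!all(vectors %in% c(0L, 1L))) stopf("agreement vectors must be 0/1")
  if (is.null(field_names)) field_names <- paste0("field", seq_len(K))
  counts <- tabulate(pattern_index(vectors, K), nbins = 2L^K)
  agreement_table(counts, field_names)
}

#' Expand a pattern table back into agreement vectors
#'
#' Inverse of [build_pattern_table()] (up to row order): each pattern row is
#' repeated its count times.
#'
#' @param table An [agreement_table()] with integer counts.
#' @return An `N` by `K` integer matrix.
#' @export
expand_patterns <- function(table) {
  stopifnot(inherits(table, "lc_agreement_table"))
  idx <- rep.int(seq_along(table$counts), table$counts)
  table$patterns[idx, , drop = FALSE]
}

#' Block, compare and tabulate raw records in one step
#'
#' Runs [block_pairs()], computes the agreement vector of every candidate
#' pair over `compare_fields` (blocking fields are excluded from the
#' agreement vector), and tabulates with [build_pattern_table()].
#'
#' @inheritParams block_pairs
#' @param compare_fields Fields entering the agreement vector.
#' @return An [agreement_table()].
#' @export
build_agreement_table <- function(records, blocking_fields, compare_fields,
                                  records2 = NULL, na_tokens = c("", "NA", "NULL")) {
  if (length(intersect(blocking_fields, compare_fields)))
    stopf("blocking fields cannot also be comparison fields")
  cfg <- field_config(compare_fields, na_tokens)
  pairs <- block_pairs(records, blocking_fields, records2, na_tokens)
  right <- if (is.null(records2)) records else records2
  canon <- function(df) vapply(compare_fields, function(f) {
    if (!f %in% names(df)) stopf("field '%s' missing from records", f)
    canonicalize(df[[f]], cfg$na_tokens)
  }, character(nrow(df)))
  A <- matrix(canon(records), nrow = nrow(records))
  B <- matrix(canon(right), nrow = nrow(right))
  a <- A[pairs[, 1L], , drop = FALSE]
  b <- B[pairs[, 2L], , drop = FALSE]
  agree <- (!is.na(a)) & (!is.na(b)) & (a == b)
  storage.mode(agree) <- "integer"
  build_pattern_table(agree, K = length(compare_fields), field_names = compare_fields)
}

#' Read an agreement-pattern table from CSV
#'
#' Expects one binary column per field plus a `count` column; rows may list
#' any subset of patterns (duplicates are summed, absent patterns get 0).
#'
#' @param path CSV file path (header row required).
#' @param field_names Field columns; default: all columns except `count_col`.
#' @param count_col Name of the count column.
#' @return An [agreement_table()].
#' @export
read_pattern_csv <- function(path, field_names = NULL, count_col = "count") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!count_col %in% names(df)) stopf("'%s' has no '%s' column", path, count_col)
  if (is.null(field_names)) field_names <- setdiff(names(df), count_col)
  K <- length(field_names)
  if (K == 0L) stopf("'%s' has no field columns", path)
  Y <- as.matrix(df[field_names])
  if (!all(Y %in% c(0, 1))) stopf("field columns of '%s' must be 0/1", path)
  storage.mode(Y) <- "integer"
  counts <- numeric(2L^K)
  idx <- pattern_index(Y, K)
  for (r in seq_along(idx)) counts[idx[r]] <- counts[idx[r]] + df[[count_col]][r]
  agreement_table(counts, field_names)
}

#' Write an agreement-pattern table to CSV
#'
#' Writes all `2^K` patterns (including zero counts) in table order.
#'
#' @param table An [agreement_table()].
#' @param path Output CSV path.
#' @export
write_pattern_csv <- function(table, path) {
  df <- as.data.frame(table$patterns)
  names(df) <- table$field_names
  df$count <- table$counts
  write_atomic(path, function(tmp) utils::write.csv(df, tmp, row.names = FALSE))
}
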