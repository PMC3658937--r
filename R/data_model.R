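#' Construct a paired count table
#'
#' A paired count table holds, for every tuple (gene, tag, locus, ...), the
#' counts observed in the first and second member of each sample pair. It is
#' stored as a wide tibble with one row per tuple: a `tuple_id` column,
#' then two columns `<pair>_a` / `<pair>_b` per sample pair.
#'
#' @param first Integer matrix or data frame (tuples x sample pairs) of
#'   counts for the first member of each pair.
#' @param second Matching matrix of counts for the second member.
#' @param tuple_ids Optional character vector of unique tuple identifiers;
#'   defaults to `t1, t2, ...`.
#' @param pairs Optional character vector of unique sample-pair labels;
#'   defaults to column names of `first`, else `p1, p2, ...`.
#'
#' @return A tibble of class `pbb_counts` with attribute `pairs`.
#' @examples
#' paired_counts(matrix(1:4, 2), matrix(4:1, 2))
#' @export
paired_counts <- function(first, second, tuple_ids = NULL, pairs = NULL) {
  first <- as.matrix(first)
  second <- as.matrix(second)
  if (!identical(dim(first), dim(second))) {
    abort("`first` and `second` must have identical dimensions.")
  }
  if (!is_count_vector(as.vector(first)) || !is_count_vector(as.vector(second))) {
    abort("negative count: all entries must be non-negative integers.")
  }
  n <- ncol(first)
  if (is.null(pairs)) pairs <- colnames(first) %||% paste0("p", seq_len(n))
  if (anyDuplicated(pairs)) abort("`pairs` labels must be unique.")
  if (length(pairs) != n) abort("`pairs` must have one label per column.")
  if (is.null(tuple_ids)) tuple_ids <- rownames(first) %||% paste0("t", seq_len(nrow(first)))
  if (anyDuplicated(tuple_ids)) abort("`tuple_ids` must be unique.")
  if (length(tuple_ids) != nrow(first)) abort("`tuple_ids` must have one id per row.")

  out <- tibble::tibble(tuple_id = as.character(tuple_ids))
  for (i in seq_len(n)) {
    out[[paste0(pairs[i], "_a")]] <- as.integer(first[, i])
    out[[paste0(pairs[i], "_b")]] <- as.integer(second[, i])
  }
  new_pbb_counts(out, pairs)
}

new_pbb_counts <- function(df, pairs) {
  structure(df,
    pairs = as.character(pairs),
    class = c("pbb_counts", class(tibble::as_tibble(df)))
  )
}

#' Coerce a wide data frame to a paired count table
#'
#' @param data Data frame with a tuple id column and `<pair>_a` / `<pair>_b`
#'   count columns for each sample pair.
#' @param tuple_id Name of the identifier column.
#' @return A `pbb_counts` tibble.
#' @export
as_paired_counts <- function(data, tuple_id = "tuple_id") {
  if (inherits(data, "pbb_counts")) return(data)
  data <- tibble::as_tibble(data)
  if (!tuple_id %in% names(data)) abort(paste0("no `", tuple_id, "` column."))
  cols <- setdiff(names(data), tuple_id)
  a_cols <- grep("_a$", cols, value = TRUE)
  b_cols <- grep("_b$", cols, value = TRUE)
  pairs <- sub("_a$", "", a_cols)
  if (!setequal(paste0(pairs, "_b"), b_cols) || length(pairs) == 0L) {
    abort("count columns must come in `<pair>_a` / `<pair>_b` pairs.")
  }
  first <- as.matrix(data[paste0(pairs, "_a")])
  second <- as.matrix(data[paste0(pairs, "_b")])
  paired_counts(first, second,
    tuple_ids = as.character(data[[tuple_id]]), pairs = pairs
  )
}

#' @export
print.pbb_counts <- function(x, ...) {
  cat("Paired count table: ", nrow(x), " tuples x ", length(pair_labels(x)),
    " sample pairs (", sum(all_zero_tuples(x)), " all-zero)\n",
    sep = ""
  )
  NextMethod()
}

#' Accessors for paired count tables
#'
#' `pair_labels()` returns the sample-pair labels; `counts_first()` and
#' `counts_second()` the count matrices for the first/second members of each
#' pair (tuples x pairs); `all_zero_tuples()` flags tuples whose counts are
#' zero in every library. All-zero tuples are retained in the container;
#' downstream steps decide how to treat them.
#'
#' @param x A `pbb_counts` table.
#' @return See individual descriptions.
#' @export
pair_labels <- function(x) attr(x, "pairs")

#' @rdname pair_labels
#' @export
counts_first <- function(x) {
  m <- as.matrix(as.data.frame(x)[paste0(pair_labels(x), "_a")])
  dimnames(m) <- list(x$tuple_id, pair_labels(x))
  m
}

#' @rdname pair_labels
#' @export
counts_second <- function(x) {
  m <- as.matrix(as.data.frame(x)[paste0(pair_labels(x), "_b")])
  dimnames(m) <- list(x$tuple_id, pair_labels(x))
  m
}

#' @rdname pair_labels
#' @export
all_zero_tuples <- function(x) {
  rowSums(counts_first(x)) + rowSums(counts_second(x)) == 0
}

#' Library scaling factors for paired libraries
#'
#' One strictly positive scaling factor per library, proportional to
#' sequencing depth: `L` for the first member of each sample pair, `L_prime`
#' for the second.
#'
#' @param L,L_prime Positive numeric vectors, one entry per sample pair.
#' @param pairs Optional sample-pair labels.
#' @return A tibble of class `pbb_scaling` with columns `pair`, `L`,
#'   `L_prime`.
#' @export
scaling_factors <- function(L, L_prime, pairs = NULL) {
  if (length(L) != length(L_prime)) abort("`L` and `L_prime` lengths differ.")
  if (any(!is.finite(L)) || any(!is.finite(L_prime)) ||
    any(L <= 0) || any(L_prime <= 0)) {
    abort("scaling factors must be strictly positive.")
  }
  if (is.null(pairs)) pairs <- paste0("p", seq_along(L))
  out <- tibble::tibble(pair = as.character(pairs), L = as.numeric(L), L_prime = as.numeric(L_prime))
  class(out) <- c("pbb_scaling", class(out))
  out
}

#' Replicate structure over sample pairs
#'
#' Sample pairs i and j belong to the same replicate group when pair j is a
#' biological replicate of pair i; the groups partition the sample pairs and
#' drive dispersion estimation.
#'
#' @param groups Either a vector of group labels, one per sample pair, or a
#'   list of disjoint index sets covering `1:n_pairs`.
#' @param n_pairs Number of sample pairs (required when `groups` is a list).
#' @return A named list of integer index vectors, class `pbb_replicates`.
#' @examples
#' replicate_structure(c("A", "A", "B", "B"))
#' @export
replicate_structure <- function(groups, n_pairs = NULL) {
  if (inherits(groups, "pbb_replicates")) return(groups)
  if (is.list(groups)) {
    sets <- lapply(groups, function(g) as.integer(g))
    if (is.null(n_pairs)) n_pairs <- max(unlist(sets))
    if (is.null(names(sets))) names(sets) <- paste0("F", seq_along(sets))
  } else {
    n_pairs <- length(groups)
    f <- factor(groups, levels = unique(groups))
    sets <- split(seq_len(n_pairs), f)
  }
  idx <- sort(unlist(sets, use.names = FALSE))
  if (length(idx) != n_pairs || !identical(idx, seq_len(as.integer(n_pairs))) ||
    anyDuplicated(unlist(sets))) {
    abort("replicate groups must be disjoint, non-empty and cover all sample pairs.")
  }
  if (any(lengths(sets) == 0L)) abort("replicate groups must be non-empty.")
  structure(sets, n_pairs = as.integer(n_pairs), class = "pbb_replicates")
}

#' @export
print.pbb_replicates <- function(x, ...) {
  cat("Replicate structure over", attr(x, "n_pairs"), "sample pairs:\n")
  for (nm in names(x)) cat(" ", nm, ":", paste(x[[nm]], collapse = ", "), "\n")
  invisible(x)
}

#' Define a model as a partition of the sample pairs
#'
#' A model is a partition of the sample pairs into sets whose data share
#' distribution parameters. A set is either FREE (its expected proportion is
#' estimated from the data) or FIXED at a constant proportion, e.g. 0.5 for
#' a one-to-one expression ratio.
#'
#' @param name Model identifier.
#' @param sets List of disjoint index sets covering all sample pairs.
#' @param fixed Numeric vector, one entry per set: `NA` for a FREE set or a
#'   fixed proportion in (0, 1).
#' @return An object of class `pbb_model`.
#' @examples
#' model_spec("no_de", list(1:4), fixed = 0.5)
#' model_spec("group_diff", list(1:2, 3:4))
#' @export
model_spec <- function(name, sets, fixed = NULL) {
  if (!is.list(sets) || length(sets) < 1L) abort("`sets` must be a non-empty list.")
  sets <- lapply(sets, function(s) sort(as.integer(s)))
  if (is.null(fixed)) fixed <- rep(NA_real_, length(sets))
  fixed <- as.numeric(fixed)
  if (length(fixed) != length(sets)) abort("`fixed` must have one entry per set.")
  bad <- !is.na(fixed) & (fixed <= 0 | fixed >= 1)
  if (any(bad)) abort("FIXED proportions must lie strictly inside (0, 1).")
  all_idx <- unlist(sets)
  if (anyDuplicated(all_idx)) abort("sets overlap: model sets must be disjoint.")
  if (any(lengths(sets) == 0L)) abort("model sets must be non-empty.")
  structure(
    list(name = as.character(name), sets = sets, fixed = fixed),
    class = "pbb_model"
  )
}

#' @export
print.pbb_model <- function(x, ...) {
  cat("Model", x$name, "\n")
  for (q in seq_along(x$sets)) {
    mode <- if (is.na(x$fixed[q])) "FREE" else paste0("FIXED ", x$fixed[q])
    cat("  E", q, " {", paste(x$sets[[q]], collapse = ","), "} ", mode, "\n", sep = "")
  }
  invisible(x)
}

n_free_sets <- function(model) sum(is.na(model$fixed))

model_n_pairs <- function(model) length(unlist(model$sets))

#' Standard model set for paired designs
#'
#' For a single-condition design: a null model (all pairs in one set with the
#' proportion fixed at 0.5, i.e. a one-to-one ratio after scaling) and a
#' consistent-ratio model (one FREE set). For a two-condition design a third
#' model with one FREE set per condition captures a ratio that differs
#' between the conditions.
#'
#' @param n_pairs Number of sample pairs.
#' @param condition Optional vector of condition labels (length `n_pairs`,
#'   at most two distinct values); when two conditions are present the
#'   group-difference model is added.
#' @return List of `pbb_model` objects.
#' @export
default_models <- function(n_pairs, condition = NULL) {
  models <- list(
    model_spec("null", list(seq_len(n_pairs)), fixed = 0.5),
    model_spec("consistent_ratio", list(seq_len(n_pairs)))
  )
  if (!is.null(condition)) {
    lev <- unique(condition)
    if (length(condition) != n_pairs) abort("`condition` must have one label per pair.")
    if (length(lev) > 2L) abort("at most two conditions are supported here.")
    if (length(lev) == 2L) {
      models <- c(models, list(model_spec(
        "group_diff",
        list(which(condition == lev[1]), which(condition == lev[2]))
      )))
    }
  }
  models
}

#' Validate a complete analysis design
#'
#' Checks that the count table, scaling factors, replicate structure and all
#' models refer to the same sample pairs, that every model partitions the
#' pairs, and that fixed proportions are admissible. Returns the bundle
#' unchanged (as a `pbb_design` list) when consistent; validation is
#' idempotent.
#'
#' @param counts A `pbb_counts` table (or a `pbb_design` bundle, returned
#'   as-is after re-checking).
#' @param scaling A `pbb_scaling` table.
#' @param reps A `pbb_replicates` structure.
#' @param models List of `pbb_model` objects (a single model is accepted).
#' @return A list of class `pbb_design` with elements `counts`, `scaling`,
#'   `reps`, `models`.
#' @export
validate_design <- function(counts, scaling, reps, models) {
  if (inherits(counts, "pbb_design")) {
    d <- counts
    return(validate_design(d$counts, d$scaling, d$reps, d$models))
  }
  counts <- as_paired_counts(counts)
  if (inherits(models, "pbb_model")) models <- list(models)
  n <- length(pair_labels(counts))
  if (!inherits(scaling, "pbb_scaling")) {
    abort("`scaling` must be built with scaling_factors().")
  }
  if (nrow(scaling) != n) abort("dimension mismatch: scaling factors vs sample pairs.")
  reps <- replicate_structure(reps, n_pairs = n)
  if (attr(reps, "n_pairs") != n) abort("dimension mismatch: replicate structure vs sample pairs.")
  for (m in models) {
    if (!inherits(m, "pbb_model")) abort("`models` must contain pbb_model objects.")
    idx <- sort(unlist(m$sets))
    if (!identical(idx, seq_len(n))) {
      abort(paste0("model `", m$name, "` does not partition the ", n, " sample pairs."))
    }
  }
  if (anyDuplicated(vapply(models, function(m) m$name, character(1)))) {
    abort("model names must be unique.")
  }
  structure(
    list(counts = counts, scaling = scaling, reps = reps, models = models),
    class = "pbb_design"
  )
}

#' Read / write paired count tables as TSV
#'
#' The on-disk format is the wide layout: a header row, one row per tuple,
#' first column `tuple_id`, then `<pair>_a` / `<pair>_b` columns. Columns are
#' matched by name, never by position. Alternatively the two members can
#' live in separate files with plain `<pair>` columns and matching headers
#' (`path_second`); the tuple ids must then agree row by row.
#'
#' @param path File path (first member, or the combined wide table).
#' @param path_second Optional file with the second member's counts.
#' @param x A `pbb_counts` table.
#' @return `read_paired_counts()` returns a `pbb_counts` tibble;
#'   `write_paired_counts()` invisibly returns `x`.
#' @export
read_paired_counts <- function(path, path_second = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (is.null(path_second)) {
    return(as_paired_counts(df))
  }
  df2 <- readr::read_tsv(path_second, show_col_types = FALSE, progress = FALSE)
  pairs <- setdiff(names(df), "tuple_id")
  if (!setequal(pairs, setdiff(names(df2), "tuple_id"))) {
    abort("the two count files must have matching pair headers.")
  }
  if (!identical(as.character(df$tuple_id), as.character(df2$tuple_id))) {
    abort("the two count files must list the same tuple ids in the same order.")
  }
  paired_counts(as.matrix(df[pairs]), as.matrix(df2[pairs]),
    tuple_ids = as.character(df$tuple_id), pairs = pairs
  )
}

#' @rdname read_paired_counts
#' @export
write_paired_counts <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(as.data.frame(x)), path, progress = FALSE)
  invisible(x)
}
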