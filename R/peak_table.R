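#' Peak table: intensities plus aligned sample and feature metadata
#'
#' A `peak_table` bundles the three pieces every pipeline stage consumes and
#' produces: a numeric intensity matrix (rows = injections, columns =
#' features, arbitrary-unit chromatographic peak areas), a sample-metadata
#' tibble aligned to the rows, and a feature-metadata tibble aligned to the
#' columns. Missing peak areas are `NA`, never 0: downstream imputation
#' models them rather than zero-filling.
#'
#' Sample metadata must carry `sample_id`, `role` (one of `"study"`, `"qc"`,
#' `"blank"`), `cultivar`, `bio_rep`, `tech_rep`, `batch` and
#' `injection_order`. Study rows must have cultivar/bio_rep/tech_rep; QC and
#' blank rows must not. `injection_order` is global and unique across rows
#' (it may be all-`NA` after technical replicates have been averaged, when
#' the injection structure no longer exists). Feature metadata carries
#' `feature_id`, `mz` (Thomson, within the instrument's 120-850 range),
#' `rt` (minutes) and `polarity` (`"positive"` or `"negative"`).
#'
#' Intensities are non-negative until [autoscale()] centres and scales them,
#' after which the `scaled` flag is set and the non-negativity invariant is
#' released.
#'
#' @param intensities Numeric matrix, rows = injections, columns = features.
#' @param samples Data frame of sample metadata, one row per matrix row.
#' @param features Data frame of feature metadata, one row per matrix column.
#' @param scaled Logical; `TRUE` once the table has been autoscaled.
#' @return A validated `peak_table` object.
#' @seealso [read_peak_table()], [write_peak_table()], [bind_polarities()]
#' @export
peak_table <- function(intensities, samples, features, scaled = FALSE) {
  samples <- tibble::as_tibble(samples)
  features <- tibble::as_tibble(features)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  rownames(intensities) <- samples$sample_id
  colnames(intensities) <- features$feature_id
  out <- structure(
    list(intensities = intensities, samples = samples, features = features,
         scaled = isTRUE(scaled)),
    class = "peak_table"
  )
  validate_peak_table(out)
}

sample_meta_cols <- c("sample_id", "role", "cultivar", "bio_rep", "tech_rep",
                      "batch", "injection_order")

#' Validate a peak table's invariants
#'
#' Checks dimension alignment, identifier uniqueness, role vocabulary, the
#' role-conditional presence of cultivar/replicate fields, uniqueness of the
#' global injection order, the m/z range, and (for unscaled tables)
#' non-negativity of observed intensities. Called by every constructor and
#' reader; exported so that externally assembled objects can be checked.
#'
#' @param x A `peak_table`.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_peak_table <- function(x) {
  stopifnot(inherits(x, "peak_table"))
  s <- x$samples
  f <- x$features
  m <- x$intensities
  missing_cols <- setdiff(sample_meta_cols, names(s))
  if (length(missing_cols) > 0)
    stop("sample metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  for (col in c("feature_id", "mz", "rt", "polarity")) {
    if (!col %in% names(f)) stop("feature metadata lacks column: ", col)
  }
  if (nrow(m) != nrow(s))
    stop("intensity rows (", nrow(m), ") != sample rows (", nrow(s), ")")
  if (ncol(m) != nrow(f))
    stop("intensity columns (", ncol(m), ") != feature rows (", nrow(f), ")")
  if (anyDuplicated(s$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(s$sample_id[duplicated(s$sample_id)]), collapse = ", "))
  if (anyDuplicated(f$feature_id))
    stop("duplicate feature_id: ",
         paste(unique(f$feature_id[duplicated(f$feature_id)]), collapse = ", "))
  bad_role <- setdiff(unique(s$role), c("study", "qc", "blank"))
  if (length(bad_role) > 0)
    stop("unknown sample role(s): ", paste(bad_role, collapse = ", "))
  is_study <- s$role == "study"
  if (any(is_study & (is.na(s$cultivar) | is.na(s$bio_rep))))
    stop("study samples must carry cultivar and bio_rep")
  if (any(!is_study & (!is.na(s$cultivar) | !is.na(s$bio_rep) | !is.na(s$tech_rep))))
    stop("qc/blank samples must not carry cultivar/bio_rep/tech_rep")
  io <- s$injection_order
  if (!all(is.na(io))) {
    if (anyNA(io)) stop("injection_order must be fully present or fully absent")
    if (anyDuplicated(io)) stop("injection_order values must be unique")
    if (any(io < 1)) stop("injection_order must be positive")
  }
  if (any(!is.na(f$mz) & (f$mz < 120 | f$mz > 850)))
    stop("feature m/z outside instrument range [120, 850]")
  if (any(!is.na(f$rt) & f$rt < 0)) stop("feature rt must be >= 0")
  bad_pol <- setdiff(unique(f$polarity), c("positive", "negative"))
  if (length(bad_pol) > 0)
    stop("unknown polarity value(s): ", paste(bad_pol, collapse = ", "))
  if (!x$scaled && any(m < 0, na.rm = TRUE))
    stop("negative intensity in unscaled table")
  invisible(x)
}

#' @export
print.peak_table <- function(x, ...) {
  roles <- table(factor(x$samples$role, levels = c("study", "qc", "blank")))
  cat(sprintf(
    "<peak_table> %d injections x %d features (%s)\n",
    nrow(x$intensities), ncol(x$intensities),
    if (x$scaled) "autoscaled" else "raw scale"))
  cat(sprintf("  roles: %d study, %d qc, %d blank\n",
              roles[["study"]], roles[["qc"]], roles[["blank"]]))
  pol <- table(factor(x$features$polarity, levels = c("positive", "negative")))
  cat(sprintf("  polarity: %d positive, %d negative\n",
              pol[["positive"]], pol[["negative"]]))
  n_na <- sum(is.na(x$intensities))
  if (n_na > 0)
    cat(sprintf("  missing cells: %d (%.1f%%)\n", n_na,
                100 * n_na / length(x$intensities)))
  invisible(x)
}

#' Number of samples / features in a peak table
#' @param x A `peak_table`.
#' @return An integer count.
#' @export
n_samples <- function(x) nrow(x$intensities)

#' @rdname n_samples
#' @export
n_features <- function(x) ncol(x$intensities)

#' Coerce a peak table to a long tibble
#'
#' One row per (sample, feature) cell, with sample and feature metadata
#' joined on, suitable for dplyr/ggplot2 work.
#'
#' @param x A `peak_table`.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `feature_id`, `intensity` and
#'   the metadata columns of both tables.
#' @method as_tibble peak_table
#' @export
as_tibble.peak_table <- function(x, ...) {
  long <- tibble::tibble(
    sample_id = rep(x$samples$sample_id, times = ncol(x$intensities)),
    feature_id = rep(x$features$feature_id, each = nrow(x$intensities)),
    intensity = as.vector(x$intensities)
  )
  long <- dplyr::left_join(long, x$samples, by = "sample_id")
  dplyr::left_join(long, x$features, by = "feature_id")
}

#' Subset a peak table
#'
#' `pt_select_features()` keeps the named features (in the given order);
#' `pt_filter_samples()` keeps samples whose role is among `roles`.
#'
#' @param x A `peak_table`.
#' @param feature_ids Character vector of feature identifiers to keep.
#' @return A `peak_table` with the subset applied.
#' @export
pt_select_features <- function(x, feature_ids) {
  idx <- match(feature_ids, x$features$feature_id)
  if (anyNA(idx))
    stop("unknown feature id(s): ",
         paste(feature_ids[is.na(idx)], collapse = ", "))
  out <- x
  out$intensities <- x$intensities[, idx, drop = FALSE]
  out$features <- x$features[idx, , drop = FALSE]
  out
}

#' @rdname pt_select_features
#' @param roles Character vector of roles to keep.
#' @export
pt_filter_samples <- function(x, roles) {
  keep <- x$samples$role %in% roles
  out <- x
  out$intensities <- x$intensities[keep, , drop = FALSE]
  out$samples <- x$samples[keep, , drop = FALSE]
  out
}

# header encoding for feature columns: "polarity|mz|rt|feature_id"
encode_feature_headers <- function(features) {
  paste(features$polarity, format(features$mz, trim = TRUE, digits = 15),
        format(features$rt, trim = TRUE, digits = 15), features$feature_id,
        sep = "|")
}

decode_feature_headers <- function(headers) {
  parts <- strsplit(headers, "|", fixed = TRUE)
  bad <- lengths(parts) != 4
  if (any(bad))
    stop("malformed feature header(s): ", paste(headers[bad], collapse = ", "))
  tibble::tibble(
    feature_id = vapply(parts, `[[`, "", 4),
    mz = as.numeric(vapply(parts, `[[`, "", 2)),
    rt = as.numeric(vapply(parts, `[[`, "", 3)),
    polarity = vapply(parts, `[[`, "", 1)
  )
}

#' Read a peak table from delimited text
#'
#' Expects the layout written by [write_peak_table()]: the reserved metadata
#' columns `sample_id, role, cultivar, bio_rep, tech_rep, batch,
#' injection_order` followed by one column per feature whose header encodes
#' its metadata as `polarity|mz|rt|feature_id`. Empty cells and the
#' `sentinel` string become missing markers (`NA`), never zero.
#'
#' @param path Path to a CSV file.
#' @param sentinel Strings (besides the empty cell) to read as missing.
#' @param scaled Logical; set when reading back an autoscaled table.
#' @return A validated [peak_table].
#' @export
read_peak_table <- function(path, sentinel = "NA", scaled = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE,
                         name_repair = "minimal")
  missing_cols <- setdiff(sample_meta_cols, names(raw))
  if (length(missing_cols) > 0)
    stop("reserved metadata column(s) absent: ",
         paste(missing_cols, collapse = ", "))
  feat_cols <- setdiff(names(raw), sample_meta_cols)
  features <- decode_feature_headers(feat_cols)
  as_na <- function(v) ifelse(v %in% c("", sentinel), NA_character_, v)
  samples <- tibble::tibble(
    sample_id = raw$sample_id,
    role = raw$role,
    cultivar = as_na(raw$cultivar),
    bio_rep = as.integer(as_na(raw$bio_rep)),
    tech_rep = as.integer(as_na(raw$tech_rep)),
    batch = as.integer(as_na(raw$batch)),
    injection_order = as.integer(as_na(raw$injection_order))
  )
  if (length(feat_cols) > 0) {
    m <- vapply(raw[feat_cols], function(v) as.numeric(as_na(v)),
                numeric(nrow(raw)))
    if (nrow(raw) == 1) m <- matrix(m, nrow = 1)
  } else {
    m <- matrix(numeric(0), nrow = nrow(raw), ncol = 0)
  }
  peak_table(m, samples, features, scaled = scaled)
}

#' Write a peak table to delimited text
#'
#' Inverse of [read_peak_table()]; missing intensities are written as the
#' sentinel `"NA"` (not zero) so that a round trip preserves missingness.
#'
#' @param table A [peak_table].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(table, path) {
  validate_peak_table(table)
  meta <- table$samples[, sample_meta_cols]
  df <- as.data.frame(table$intensities)
  names(df) <- encode_feature_headers(table$features)
  out <- dplyr::bind_cols(meta, tibble::as_tibble(df, .name_repair = "minimal"))
  readr::write_csv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Bind positive- and negative-polarity peak tables by column
#'
#' The final analysis table joins the two acquisition polarities: rows are
#' aligned by `sample_id` (order of `pos` wins) and feature identifiers are
#' namespaced with `pos_` / `neg_` prefixes so uniqueness holds across the
#' bound table. Both inputs must hold exactly the same sample set and be at
#' the same processing stage.
#'
#' @param pos,neg `peak_table`s of the two polarities.
#' @return A `peak_table` with `n_features(pos) + n_features(neg)` columns.
#' @export
bind_polarities <- function(pos, neg) {
  validate_peak_table(pos); validate_peak_table(neg)
  only_pos <- setdiff(pos$samples$sample_id, neg$samples$sample_id)
  only_neg <- setdiff(neg$samples$sample_id, pos$samples$sample_id)
  if (length(only_pos) > 0 || length(only_neg) > 0)
    stop("sample sets differ; only in pos: [",
         paste(only_pos, collapse = ", "), "], only in neg: [",
         paste(only_neg, collapse = ", "), "]")
  if (pos$scaled != neg$scaled)
    stop("tables are at different processing stages (scaled flag differs)")
  idx <- match(pos$samples$sample_id, neg$samples$sample_id)
  prefix_of <- function(tab) {
    pol <- unique(tab$features$polarity)
    if (length(pol) != 1)
      stop("each input table must hold a single polarity")
    c(positive = "pos_", negative = "neg_")[[pol]]
  }
  pf <- pos$features; nf <- neg$features
  if (nrow(pf) > 0 && nrow(nf) > 0 && prefix_of(pos) == prefix_of(neg))
    stop("the two tables have the same polarity")
  pf$feature_id <- paste0(if (nrow(pf)) prefix_of(pos) else "", pf$feature_id)
  nf$feature_id <- paste0(if (nrow(nf)) prefix_of(neg) else "", nf$feature_id)
  m <- cbind(pos$intensities, neg$intensities[idx, , drop = FALSE])
  peak_table(m, pos$samples, dplyr::bind_rows(pf, nf), scaled = pos$scaled)
}
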