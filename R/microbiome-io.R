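# Reading, merging, filtering, binarizing and stratifying MetaPhlAn-style
# merged relative-abundance tables. All operations conserve per-sample RA
# totals: species removed by a filter have their abundance reassigned to the
# reserved "unclassified" row.

UNCLASSIFIED <- "unclassified"

is_species_lineage <- function(x) {
  grepl("s__", x, fixed = TRUE) & !grepl("t__", x, fixed = TRUE)
}

#' Construct an abundance table
#'
#' Species-by-samples relative abundances (percent, in \[0, 100\]) with a
#' reserved `"unclassified"` row holding the remainder of each sample's
#' profile. Row names are taxonomy lineage strings (rank-prefixed,
#' pipe-separated, species level).
#'
#' @param values Numeric matrix, species in rows (lineage row names), samples
#'   in columns. An `"unclassified"` row is added (zero) when absent.
#' @param study Optional study id per sample (named or positional), used by
#'   [merge_profiles()].
#' @return An object of class `abundance_table` with fields `values` and
#'   `study`.
#' @export
abundance_table <- function(values, study = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_hd("abundances must be numeric")
  if (is.null(rownames(values))) stop_hd("rows must be named by lineage")
  if (is.null(colnames(values))) stop_hd("columns must be named by sample id")
  rn <- rownames(values)
  rn[tolower(rn) %in% c("unclassified", "unknown")] <- UNCLASSIFIED
  rownames(values) <- rn
  if (anyDuplicated(rownames(values))) stop_hd("row identifiers must be unique")
  if (anyDuplicated(colnames(values))) stop_hd("sample ids must be unique")
  if (any(values < 0)) stop_hd("relative abundances must be >= 0")
  if (!(UNCLASSIFIED %in% rownames(values))) {
    values <- rbind(values,
                    matrix(0, 1, ncol(values),
                           dimnames = list(UNCLASSIFIED, colnames(values))))
  }
  totals <- colSums(values)
  if (any(totals > 100 + 1e-6)) {
    stop_hd("per-sample abundance totals exceed 100%: ",
            paste(colnames(values)[totals > 100 + 1e-6], collapse = ", "))
  }
  if (!is.null(study)) {
    if (length(study) == 1) study <- rep(study, ncol(values))
    if (length(study) != ncol(values)) {
      stop_hd("`study` must have one entry per sample")
    }
    study <- stats::setNames(as.character(study), colnames(values))
  }
  structure(list(values = values, study = study), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("Abundance table:", nrow(x$values) - 1L, "species x",
      ncol(x$values), "samples (+ unclassified row)\n")
  if (!is.null(x$study)) {
    cat("  studies:", paste(unique(x$study), collapse = ", "), "\n")
  }
  invisible(x)
}

species_rows <- function(table) {
  setdiff(rownames(table$values), UNCLASSIFIED)
}

#' Read a merged MetaPhlAn-style profile table
#'
#' Expects a TSV with the taxonomy lineage in the first column and one column
#' per sample. Only species-level rows are retained (lineage containing
#' `s__` without a strain `t__` suffix) plus the reserved
#' `unclassified`/`UNKNOWN` row; other taxonomic ranks are dropped.
#'
#' @param path Path to the TSV file.
#' @param study Optional study id to attach to all samples.
#' @return An [abundance_table()].
#' @export
read_profiles <- function(path, study = NULL) {
  raw <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop_hd("profile table needs a lineage column plus samples")
  names(raw)[1] <- sub("^#\\s*", "", names(raw)[1])
  lineage <- as.character(raw[[1]])
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (anyNA(num) && !anyNA(v)) {
        bad <- which(is.na(num))[1]
        stop_hd("non-numeric abundance in column '", names(vals)[j],
                "', row ", bad, " ('", v[bad], "')")
      }
      vals[[j]] <- num
    }
  }
  keep <- is_species_lineage(lineage) |
    tolower(lineage) %in% c("unclassified", "unknown")
  m <- as.matrix(vals[keep, , drop = FALSE])
  rownames(m) <- lineage[keep]
  abundance_table(m, study = study)
}

#' Write an abundance table as TSV
#'
#' @param table An [abundance_table()].
#' @param path Output path. The lineage column is named `clade_name`.
#' @export
write_profiles <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  df <- data.frame(clade_name = rownames(table$values), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' A TSV with header columns `sample_id`, `class` and optionally `sex`,
#' `age`, `study`. Samples labeled `adenoma` are dropped with a warning: the
#' case/control contrast is between disease and control classes only.
#'
#' @param path Path to the metadata TSV.
#' @return A data frame with one row per retained sample.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  required <- c("sample_id", "class")
  missing <- setdiff(required, names(md))
  if (length(missing)) {
    stop_hd("metadata is missing column(s): ", paste(missing, collapse = ", "))
  }
  adenoma <- tolower(md$class) == "adenoma"
  if (any(adenoma)) {
    warning(sum(adenoma), " adenoma sample(s) dropped from the metadata")
    md <- md[!adenoma, , drop = FALSE]
  }
  if ("age" %in% names(md) && any(!is.na(md$age) & md$age < 0)) {
    stop_hd("ages must be non-negative")
  }
  md
}

#' Merge per-study tables, keeping species detected in every study
#'
#' Species with a positive abundance in at least one sample of *every* study
#' are retained. Each dropped species' per-sample abundance is added to that
#' sample's `unclassified` row, so per-sample totals are conserved exactly.
#'
#' @param tables List of [abundance_table()]s, each with its `study` set (or
#'   a named list, in which case names are used as study ids). Sample ids
#'   must be disjoint across tables.
#' @return The merged [abundance_table()].
#' @export
merge_profiles <- function(tables) {
  if (!is.list(tables) || length(tables) == 0) {
    stop_hd("`tables` must be a non-empty list of abundance tables")
  }
  tables <- lapply(seq_along(tables), function(i) {
    tb <- tables[[i]]
    stopifnot(inherits(tb, "abundance_table"))
    if (is.null(tb$study)) {
      id <- if (!is.null(names(tables))) names(tables)[i] else as.character(i)
      tb$study <- stats::setNames(rep(id, ncol(tb$values)),
                                  colnames(tb$values))
    }
    tb
  })
  all_samples <- unlist(lapply(tables, function(tb) colnames(tb$values)))
  if (anyDuplicated(all_samples)) {
    stop_hd("duplicate sample ids across studies: ",
            paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "))
  }
  detected <- lapply(tables, function(tb) {
    sp <- species_rows(tb)
    sp[rowSums(tb$values[sp, , drop = FALSE] > 0) > 0]
  })
  keep <- Reduce(intersect, detected)
  merged <- lapply(tables, function(tb) {
    sp <- species_rows(tb)
    dropped <- setdiff(sp, keep)
    uncl <- tb$values[UNCLASSIFIED, ] +
      colSums(tb$values[dropped, , drop = FALSE])
    block <- matrix(0, nrow = length(keep), ncol = ncol(tb$values),
                    dimnames = list(keep, colnames(tb$values)))
    have <- intersect(keep, sp)
    block[have, ] <- tb$values[have, , drop = FALSE]
    rbind(block, matrix(uncl, 1, dimnames = list(UNCLASSIFIED, NULL)))
  })
  values <- do.call(cbind, merged)
  study <- do.call(c, lapply(tables, function(tb) tb$study))
  abundance_table(values, study = study)
}

#' Filter low-abundance and low-prevalence species
#'
#' Two filters applied in order, each reassigning the removed species'
#' abundance to `unclassified`: (1) species whose *maximum* relative
#' abundance across samples is below `ra_threshold` percent; (2) species
#' detected (RA > 0) in fewer than `prevalence_threshold` percent of the
#' samples.
#'
#' @param table An [abundance_table()].
#' @param ra_threshold Minimum peak abundance in percent (default 1).
#' @param prevalence_threshold Minimum detection prevalence in percent
#'   (default 5).
#' @return The filtered [abundance_table()].
#' @export
filter_species <- function(table, ra_threshold = 1, prevalence_threshold = 5) {
  stopifnot(inherits(table, "abundance_table"))
  if (ra_threshold < 0 || ra_threshold > 100 ||
      prevalence_threshold < 0 || prevalence_threshold > 100) {
    stop_hd("thresholds must be in [0, 100]")
  }
  drop_rows <- function(tb, drop) {
    if (length(drop) == 0) return(tb)
    vals <- tb$values
    vals[UNCLASSIFIED, ] <- vals[UNCLASSIFIED, ] +
      colSums(vals[drop, , drop = FALSE])
    vals <- vals[setdiff(rownames(vals), drop), , drop = FALSE]
    abundance_table(vals, study = tb$study)
  }
  sp <- species_rows(table)
  peak <- apply(table$values[sp, , drop = FALSE], 1, max)
  table <- drop_rows(table, sp[peak < ra_threshold])
  sp <- species_rows(table)
  prev <- 100 * rowSums(table$values[sp, , drop = FALSE] > 0) /
    ncol(table$values)
  drop_rows(table, sp[prev < prevalence_threshold])
}

#' Binarize abundances to presence/absence
#'
#' A value becomes 1 when the relative abundance is strictly positive,
#' otherwise 0. For an [abundance_table()] the `unclassified` row is dropped
#' (it is not a feature); a plain matrix is binarized in place, making the
#' operation idempotent.
#'
#' @param x An [abundance_table()] or a numeric matrix.
#' @return A numeric 0/1 matrix (species x samples for abundance tables).
#' @export
binarize <- function(x) {
  if (inherits(x, "abundance_table")) {
    m <- x$values[species_rows(x), , drop = FALSE]
  } else {
    m <- as.matrix(x)
  }
  (m > 0) + 0
}

#' Stratify samples by sex or age category
#'
#' Splits a table into named sub-tables: `male`/`female` for `by = "sex"`, or
#' `adult` (age <= 65) / `senior` (age > 65) for `by = "age"`. Samples with a
#' missing or unknown key are excluded with a warning; the feature set is
#' unchanged.
#'
#' @param table An [abundance_table()].
#' @param metadata Metadata data frame (see [read_metadata()]) covering the
#'   table's samples.
#' @param by `"sex"` or `"age"`.
#' @return Named list of [abundance_table()]s.
#' @export
stratify_samples <- function(table, metadata, by = c("sex", "age")) {
  stopifnot(inherits(table, "abundance_table"))
  by <- match.arg(by)
  if (!(by %in% names(metadata))) {
    stop_hd("metadata has no '", by, "' column")
  }
  ids <- colnames(table$values)
  m <- metadata[match(ids, metadata$sample_id), ]
  if (by == "sex") {
    key <- tolower(as.character(m$sex))
    key[!(key %in% c("male", "female"))] <- NA
    strata <- c("male", "female")
  } else {
    age <- suppressWarnings(as.numeric(m$age))
    key <- ifelse(is.na(age), NA, ifelse(age <= 65, "adult", "senior"))
    strata <- c("adult", "senior")
  }
  if (anyNA(key)) {
    warning(sum(is.na(key)), " sample(s) without a usable '", by,
            "' value excluded from the stratification")
  }
  out <- lapply(strata, function(s) {
    cols <- ids[!is.na(key) & key == s]
    abundance_table(table$values[, cols, drop = FALSE],
                    study = table$study[cols])
  })
  stats::setNames(out, strata)
}

#' Convert an abundance table to a classifier-ready dataset
#'
#' Transposes to samples-by-features, optionally binarizes, drops the
#' `unclassified` row, and attaches class labels from the metadata.
#'
#' @param table An [abundance_table()].
#' @param metadata Metadata data frame with `sample_id` and `class`; every
#'   table sample must be covered.
#' @param binary Convert to presence/absence (default `TRUE`)?
#' @return A [labeled_dataset()].
#' @export
as_labeled_dataset <- function(table, metadata, binary = TRUE) {
  stopifnot(inherits(table, "abundance_table"))
  ids <- colnames(table$values)
  m <- metadata[match(ids, metadata$sample_id), ]
  if (anyNA(m$class)) {
    stop_hd("metadata lacks a class for sample(s): ",
            paste(ids[is.na(m$class)], collapse = ", "))
  }
  feats <- table$values[species_rows(table), , drop = FALSE]
  if (binary) feats <- binarize(feats)
  labeled_dataset(t(feats), labels = m$class, sample_ids = ids)
}
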