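#' Read a multi-region somatic mutation table
#'
#' Reads the package's tab-separated mutation dialect: one row per observed
#' mutation call in one tumor region, UTF-8, a single header line, missing
#' values written as `NA`. Mandatory columns are `patient_id`, `region_id`,
#' `gene`, `protein_change`, `vaf`, `is_driver`; `ccf` and `clonality` are
#' optional and tolerated as missing. Rows whose `vaf` (or `ccf`, when
#' present) falls outside \[0, 1\] are rejected, not silently kept: they are
#' dropped from the result, reported via `message()`, and returned in the
#' `"rejected"` attribute with a per-row reason.
#'
#' @param path Path to a tab-separated file.
#' @param quiet Suppress row-rejection messages?
#' @return A `data.frame` of validated mutation calls with attribute
#'   `"rejected"` (a `data.frame` of dropped rows and reasons, possibly
#'   empty). `clonality` is one of `"clonal"`, `"subclonal"`, `NA`.
#' @seealso [write_mutation_table()], [read_clinical_table()],
#'   [read_cna_table()]
#' @export
read_mutation_table <- function(path, quiet = FALSE) {
  df <- read_tsv_strict(path)
  need <- c("patient_id", "region_id", "gene", "protein_change", "vaf",
            "is_driver")
  check_columns(df, need, path)
  if (!"ccf" %in% names(df)) df$ccf <- NA_real_
  if (!"clonality" %in% names(df)) df$clonality <- NA_character_

  df$vaf <- as.numeric(df$vaf)
  df$ccf <- as.numeric(df$ccf)
  df$is_driver <- as_boolean(df$is_driver)
  df$protein_change[is.na(df$protein_change)] <- ""

  bad <- rep("", nrow(df))
  bad[is.na(df$vaf) | df$vaf < 0 | df$vaf > 1] <- "vaf outside [0,1]"
  okc <- is.na(df$ccf) | (df$ccf >= 0 & df$ccf <= 1)
  bad[!okc & !nzchar(bad)] <- "ccf outside [0,1]"
  okl <- is.na(df$clonality) | df$clonality %in% c("clonal", "subclonal")
  bad[!okl & !nzchar(bad)] <- "unknown clonality label"

  finish_table(df, bad, path, quiet,
               cols = c("patient_id", "region_id", "gene", "protein_change",
                        "vaf", "ccf", "is_driver", "clonality"))
}

#' Read a per-region copy-number segment table
#'
#' Columns: `patient_id`, `region_id`, `chrom`, `start`, `end`, `cn_state`.
#' Coordinates are 0-based half-open (BED convention); rows with
#' `start >= end` or non-integer coordinates are rejected and logged.
#'
#' @inheritParams read_mutation_table
#' @return A `data.frame` of segments with a `"rejected"` attribute.
#' @export
read_cna_table <- function(path, quiet = FALSE) {
  df <- read_tsv_strict(path)
  need <- c("patient_id", "region_id", "chrom", "start", "end", "cn_state")
  check_columns(df, need, path)
  df$start <- suppressWarnings(as.integer(df$start))
  df$end <- suppressWarnings(as.integer(df$end))
  df$cn_state <- suppressWarnings(as.integer(df$cn_state))

  bad <- rep("", nrow(df))
  bad[is.na(df$start) | is.na(df$end)] <- "non-integer coordinates"
  bad[!nzchar(bad) & df$start >= df$end] <- "start >= end"
  bad[!nzchar(bad) & df$start < 0] <- "negative start"
  bad[!nzchar(bad) & is.na(df$cn_state)] <- "non-integer cn_state"
  finish_table(df, bad, path, quiet, cols = need)
}

#' Read a clinical table
#'
#' Columns: `patient_id`, `dfs_time` (days), `dfs_event`, `tumor_size` (mm),
#' `n_regions_sampled`, `stage`, `pleural_invasion`, `vascular_invasion`,
#' `adjuvant_therapy`, `histology`. Disease-free survival time must be
#' non-negative and tumor size positive when present; offending rows are
#' rejected and logged. Boolean-like fields accept TRUE/FALSE, 0/1, yes/no
#' and are coerced (coercions of unparseable values to `NA` count as
#' rejections only for the mandatory `dfs_event`).
#'
#' @inheritParams read_mutation_table
#' @return A `data.frame` of clinical records with a `"rejected"` attribute.
#' @export
read_clinical_table <- function(path, quiet = FALSE) {
  df <- read_tsv_strict(path)
  need <- c("patient_id", "dfs_time", "dfs_event", "tumor_size",
            "n_regions_sampled", "stage", "histology")
  check_columns(df, need, path)
  for (opt in c("pleural_invasion", "vascular_invasion", "adjuvant_therapy"))
    if (!opt %in% names(df)) df[[opt]] <- NA
  df$dfs_time <- as.numeric(df$dfs_time)
  df$tumor_size <- as.numeric(df$tumor_size)
  df$n_regions_sampled <- suppressWarnings(as.integer(df$n_regions_sampled))
  for (b in c("dfs_event", "pleural_invasion", "vascular_invasion",
              "adjuvant_therapy"))
    df[[b]] <- as_boolean(df[[b]])

  bad <- rep("", nrow(df))
  bad[is.na(df$dfs_time) | df$dfs_time < 0] <- "dfs_time missing or negative"
  bad[!nzchar(bad) & is.na(df$dfs_event)] <- "dfs_event not boolean"
  bad[!nzchar(bad) & !is.na(df$tumor_size) & df$tumor_size <= 0] <-
    "tumor_size not positive"
  bad[!nzchar(bad) & (is.na(df$n_regions_sampled) |
                        df$n_regions_sampled < 1)] <-
    "n_regions_sampled missing or < 1"
  finish_table(df, bad, path, quiet,
               cols = c("patient_id", "dfs_time", "dfs_event", "tumor_size",
                        "n_regions_sampled", "stage", "pleural_invasion",
                        "vascular_invasion", "adjuvant_therapy", "histology"))
}

#' Write pipeline tables
#'
#' Writers for the tab-separated dialect read by [read_mutation_table()],
#' [read_cna_table()] and [read_clinical_table()]: UTF-8, one header line,
#' `NA` for missing values, no quoting. Writing then reading is the identity
#' on validated records.
#'
#' @param x A `data.frame` as returned by the corresponding reader (or the
#'   synthetic cohort generator).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(x, path) write_tsv(x, path)

#' @rdname write_mutation_table
#' @export
write_cna_table <- function(x, path) write_tsv(x, path)

#' @rdname write_mutation_table
#' @export
write_clinical_table <- function(x, path) write_tsv(x, path)

#' Write and read trees in Newick format
#'
#' `write_tree_newick()` serializes an [evo_tree()] with branch lengths equal
#' to the integer per-edge mutation counts; internal node ids are written as
#' node labels so the tree structure round-trips exactly, including the
#' unifurcating trunk below the root. `read_tree_newick()` parses with
#' \pkg{ape} and returns an `evo_tree`.
#'
#' @param tree An `evo_tree` with uniquely named leaves.
#' @param path File to write to / read from.
#' @param outgroup Outgroup leaf id to flag on the tree read back, or `NA`.
#' @return `write_tree_newick()` returns `path` invisibly;
#'   `read_tree_newick()` returns an `evo_tree`.
#' @examples
#' f <- tempfile(fileext = ".nwk")
#' write_tree_newick(demo_tree(), f)
#' readLines(f)
#' @export
write_tree_newick <- function(tree, path) {
  stopifnot(inherits(tree, "evo_tree"))
  lv <- tree_leaves(tree)
  if (anyDuplicated(lv)) stop("duplicate leaf names")
  writeLines(stored_newick(tree), path)
  invisible(path)
}

#' @rdname write_tree_newick
#' @export
read_tree_newick <- function(path, outgroup = NA_character_) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("could not parse Newick file: ", path)
  evo_tree_from_phylo(phy, outgroup = outgroup)
}

## ---- internal helpers -------------------------------------------------

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    na.strings = "NA", colClasses = "character",
                    check.names = TRUE, fileEncoding = "UTF-8",
                    stringsAsFactors = FALSE)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

check_columns <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing mandatory column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
}

as_boolean <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

finish_table <- function(df, bad, path, quiet, cols) {
  rej <- df[nzchar(bad), , drop = FALSE]
  if (nrow(rej)) {
    rej$reason <- bad[nzchar(bad)]
    rej$row <- which(nzchar(bad))
    if (!quiet)
      message("rejected ", nrow(rej), " row(s) from ", basename(path), ": ",
              paste(unique(rej$reason), collapse = "; "))
  } else {
    rej$reason <- character(0)
    rej$row <- integer(0)
  }
  out <- df[!nzchar(bad), cols, drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rej
  out
}
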