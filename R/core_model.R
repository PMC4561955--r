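SAMPLE_LABELS <- c("P1", "P2", "F1", "F2")

GROUP_LEVELS <- c("ADDITIVITY", "ELD_P1", "ELD_P2", "TRANSGRESSIVE_UP",
                  "TRANSGRESSIVE_DOWN", "CONSERVED", "AMBIGUOUS")

#' Construct a count table for a hybrid-parent trio experiment
#'
#' A \code{count_table} holds non-negative integer fragment counts for a set
#' of genes (or miRNAs) across the four unreplicated libraries of a
#' hybrid-trio design: maternal parent \code{P1}, paternal parent \code{P2},
#' and the two hybrid generations \code{F1} and \code{F2}. Sample roles are
#' carried by label, not column position, because downstream classification
#' is parent-polarized.
#'
#' @param counts integer matrix, genes x samples; all cells non-negative
#'   whole numbers.
#' @param gene_ids character vector of unique identifiers, one per row.
#' @param sample_labels character vector of unique labels, one per column.
#' @param library_sizes optional per-sample totals of mapped fragments. The
#'   default is the column sum; an explicit value may exceed the column sum
#'   (the mapped-fragment total can exceed what the table tabulates) but may
#'   not fall below it.
#' @return an object of class \code{count_table} with elements
#'   \code{counts}, \code{gene_ids}, \code{sample_labels},
#'   \code{library_sizes}.
#' @export
count_table <- function(counts, gene_ids, sample_labels,
                        library_sizes = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != floor(counts))) {
    stop("counts must be finite, non-negative and integral", call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  sample_labels <- as.character(sample_labels)
  if (length(gene_ids) != nrow(counts)) {
    stop("gene_ids length must match row count", call. = FALSE)
  }
  if (length(sample_labels) != ncol(counts)) {
    stop("sample_labels length must match column count", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene_id: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_labels)) {
    stop("sample labels must be unique", call. = FALSE)
  }
  csums <- colSums(counts)
  if (is.null(library_sizes)) {
    library_sizes <- csums
  } else {
    library_sizes <- as.numeric(library_sizes)
    if (length(library_sizes) != ncol(counts)) {
      stop("library_sizes length must match sample count", call. = FALSE)
    }
    if (any(library_sizes <= 0)) {
      stop("library_sizes must be positive", call. = FALSE)
    }
    if (any(library_sizes < csums)) {
      stop("explicit library_sizes may not be below the column sums",
           call. = FALSE)
    }
  }
  names(library_sizes) <- sample_labels
  dimnames(counts) <- list(gene_ids, sample_labels)
  structure(list(counts = counts, gene_ids = gene_ids,
                 sample_labels = sample_labels,
                 library_sizes = library_sizes),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", length(x$gene_ids), "features x",
      length(x$sample_labels), "samples (",
      paste(x$sample_labels, collapse = ", "), ")\n")
  cat("library sizes:", paste(format(x$library_sizes), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Analysis configuration
#'
#' Thresholds and plumbing constants shared by every stage. Defaults follow
#' the decision rules of the source study: protein-coding DE at
#' FDR <= 0.001 with fold change > 2, miRNA DE at adjusted p < 0.05, and an
#' FPKM >= 1 presence call.
#'
#' @param fdr_gene FDR threshold for gene-level comparisons (default 0.001).
#' @param fdr_mirna adjusted-p threshold for the miRNA layer (default 0.05).
#' @param fc_threshold fold-change gate, must exceed 1 (default 2).
#' @param min_fpkm_expressed FPKM presence cutoff (default 1).
#' @param pseudocount added to normalized counts before log fold change
#'   (default 1).
#' @param seed integer seed recorded in run manifests.
#' @return a list of class \code{analysis_config}.
#' @export
analysis_config <- function(fdr_gene = 0.001, fdr_mirna = 0.05,
                            fc_threshold = 2.0, min_fpkm_expressed = 1.0,
                            pseudocount = 1.0, seed = 1L) {
  stopifnot(fdr_gene > 0, fdr_mirna > 0, fc_threshold > 1,
            min_fpkm_expressed > 0, pseudocount > 0)
  structure(list(fdr_gene = fdr_gene, fdr_mirna = fdr_mirna,
                 fc_threshold = fc_threshold,
                 min_fpkm_expressed = min_fpkm_expressed,
                 pseudocount = pseudocount, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Unknown keys are rejected so that typos do not silently fall back to
#' defaults.
#'
#' @param path YAML file with any subset of the \code{\link{analysis_config}}
#'   fields.
#' @return an \code{analysis_config}.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(analysis_config, vals)
}

read_tsv_checked <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!nrow(df) && !ncol(df)) stop("empty table: ", path, call. = FALSE)
  df
}

#' Read a gene-by-sample count table from TSV
#'
#' The file must be tab-separated with a \code{gene_id} column followed by
#' one column per sample; \code{#} lines are ignored. Cells must be
#' non-negative integers. Input gene order is preserved.
#'
#' @param path TSV file path.
#' @param expected_samples sample labels that must be present as columns
#'   (default the trio quartet P1, P2, F1, F2).
#' @param library_sizes optional explicit mapped-fragment totals, named by
#'   sample.
#' @return a \code{\link{count_table}} restricted to \code{expected_samples},
#'   in that order.
#' @export
read_count_table <- function(path, expected_samples = SAMPLE_LABELS,
                             library_sizes = NULL) {
  df <- read_tsv_checked(path)
  if (!"gene_id" %in% names(df)) {
    stop("count table must have a gene_id column: ", path, call. = FALSE)
  }
  missing <- setdiff(expected_samples, names(df))
  if (length(missing)) {
    stop("count table is missing sample column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mat <- df[, expected_samples, drop = FALSE]
  for (j in seq_along(mat)) {
    col <- mat[[j]]
    if (!is.numeric(col) || any(!is.finite(col)) || any(col < 0) ||
        any(col != floor(col))) {
      stop("non-integer or negative count in column ",
           expected_samples[j], call. = FALSE)
    }
  }
  if (!is.null(library_sizes)) {
    library_sizes <- library_sizes[expected_samples]
  }
  count_table(as.matrix(mat), df$gene_id, expected_samples,
              library_sizes = library_sizes)
}

#' Read per-gene metadata (length and term annotations) from TSV
#'
#' @param path TSV with columns \code{gene_id}, \code{length_bp} and
#'   \code{go_terms} (semicolon-separated term identifiers, may be empty).
#' @return data frame keyed by \code{gene_id} with integer \code{length_bp}
#'   and a list-column \code{go_terms} of character vectors.
#' @export
read_gene_meta <- function(path) {
  df <- read_tsv_checked(path)
  need <- c("gene_id", "length_bp", "go_terms")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("gene metadata is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(df$length_bp)) || any(df$length_bp < 1) ||
      any(df$length_bp != floor(df$length_bp))) {
    stop("length_bp must be a positive integer for every gene",
         call. = FALSE)
  }
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id in metadata", call. = FALSE)
  }
  terms <- lapply(as.character(df$go_terms), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) character(0)
    else unique(trimws(strsplit(s, ";", fixed = TRUE)[[1]]))
  })
  out <- data.frame(gene_id = as.character(df$gene_id),
                    length_bp = as.integer(df$length_bp),
                    stringsAsFactors = FALSE)
  out$go_terms <- terms
  rownames(out) <- out$gene_id
  out
}

#' Read a miRNA-to-target map from TSV
#'
#' @param path TSV with columns \code{mirna_id} and \code{gene_id}; the map
#'   is many-to-many and duplicate pairs are dropped.
#' @return data frame of unique (mirna_id, gene_id) links.
#' @export
read_target_map <- function(path) {
  df <- read_tsv_checked(path)
  missing <- setdiff(c("mirna_id", "gene_id"), names(df))
  if (length(missing)) {
    stop("target map is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- unique(df[, c("mirna_id", "gene_id")])
  df$mirna_id <- as.character(df$mirna_id)
  df$gene_id <- as.character(df$gene_id)
  rownames(df) <- NULL
  df
}

format_sig6 <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
}

write_result_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format_sig6(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Write a count table to TSV
#'
#' Inverse of \code{\link{read_count_table}}; a write-then-read round trip
#' reproduces the table exactly.
#'
#' @param ct a \code{count_table}.
#' @param path output TSV path.
#' @export
write_count_table <- function(ct, path) {
  df <- data.frame(gene_id = ct$gene_ids,
                   as.data.frame(ct$counts, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write result tables plus a JSON run manifest
#'
#' Each table is written as TSV with deterministic column order, rows sorted
#' by their leading id column, and doubles at 6 significant digits; the
#' manifest records the configuration, seed and md5 digests of the named
#' input files, so identical inputs and config yield byte-identical output.
#'
#' @param tables named list of data frames.
#' @param out_dir output directory, created if needed.
#' @param config an \code{\link{analysis_config}}.
#' @param input_paths character vector of input files to digest into the
#'   manifest (optional).
#' @return invisibly, the manifest list.
#' @export
write_results <- function(tables, out_dir, config = analysis_config(),
                          input_paths = character(0)) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  written <- character(0)
  for (nm in sort(names(tables))) {
    df <- tables[[nm]]
    if (nrow(df) > 1) {
      df <- df[order(df[[1]], method = "radix"), , drop = FALSE]
    }
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    write_result_tsv(df, path)
    written <- c(written, path)
  }
  digests <- if (length(input_paths)) {
    d <- tools::md5sum(input_paths)
    as.list(stats::setNames(unname(d), basename(input_paths)))
  } else list()
  manifest <- list(tool = "hybridELD",
                   version = as.character(utils::packageVersion("hybridELD")),
                   config = unclass(config), seed = config$seed,
                   input_digests = digests,
                   tables = stats::setNames(
                     lapply(tables, nrow), names(tables)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
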