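#' Construct a differential-expression result table
#'
#' @param df data frame with columns `gene_id`, `log2fc`, `padj` and
#'   optionally `biotype`. `gene_id` must be unique; `padj` values must be
#'   in `[0, 1]` or `NA`.
#' @param label condition label for the table.
#' @return A data frame of class `deg_table`.
#' @export
deg_table <- function(df, label = "") {
  need <- c("gene_id", "log2fc", "padj")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("DE table missing columns: ",
                         paste(miss, collapse = ", "))
  df$gene_id <- as.character(df$gene_id)
  df$log2fc <- as.numeric(df$log2fc)
  df$padj <- as.numeric(df$padj)
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id in DE table: ",
         df$gene_id[anyDuplicated(df$gene_id)])
  }
  bad <- !is.na(df$padj) & (df$padj < 0 | df$padj > 1)
  if (any(bad)) stop("padj outside [0, 1] for gene(s): ",
                     paste(utils::head(df$gene_id[bad], 3), collapse = ", "))
  if (!"biotype" %in% names(df)) df$biotype <- NA_character_
  attr(df, "label") <- as.character(label)
  class(df) <- c("deg_table", "data.frame")
  df
}

# DESeq2-style and common column aliases
DEG_ALIASES <- list(
  gene_id = c("gene_id", "gene", "gene_name", "ensembl_gene_id", "id"),
  log2fc = c("log2fc", "log2foldchange", "logfc", "lfc"),
  padj = c("padj", "fdr", "adj_p", "adj.p.val", "qvalue", "q_value"),
  biotype = c("biotype", "gene_biotype")
)

#' Read a differential-expression result table
#'
#' Reads a CSV/TSV with header; DESeq2-style column names
#' (`log2FoldChange`, `padj`) and common aliases are accepted
#' (case-insensitive).
#'
#' @param path file path (`.csv` or `.tsv`/`.txt`, separator inferred).
#' @param label condition label.
#' @return A `deg_table`.
#' @export
read_deg_table <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, quote = "\""),
    error = function(e) stop("parse error reading DE table ", path, ": ",
                             conditionMessage(e)))
  lownames <- tolower(names(df))
  out <- list()
  for (field in names(DEG_ALIASES)) {
    hit <- which(lownames %in% DEG_ALIASES[[field]])
    if (length(hit)) out[[field]] <- df[[hit[1]]]
  }
  for (field in c("gene_id", "log2fc", "padj")) {
    if (is.null(out[[field]])) {
      stop("DE table ", path, " lacks a recognizable '", field,
           "' column (found: ", paste(names(df), collapse = ", "), ")")
    }
  }
  deg_table(as.data.frame(out, stringsAsFactors = FALSE), label = label)
}

#' Filter a DE table to significant records
#'
#' Keeps records with `padj` present and strictly below `alpha`; records
#' with missing `padj` are excluded.
#'
#' @param t a `deg_table`.
#' @param alpha significance threshold in (0, 1); default 0.05.
#' @return The filtered `deg_table` (possibly empty).
#' @export
filter_significant <- function(t, alpha = 0.05) {
  stopifnot(inherits(t, "deg_table"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  keep <- !is.na(t$padj) & t$padj < alpha
  out <- t[keep, , drop = FALSE]
  attr(out, "label") <- attr(t, "label")
  class(out) <- class(t)
  out
}

#' Label DE records by fold-change direction
#'
#' Adds a `direction` column (`"up"` for `log2fc > 0`, `"down"` for
#' `log2fc < 0`); records with `log2fc == 0` are excluded, their count kept
#' in attribute `n_zero_excluded` (with a warning when non-zero).
#'
#' @param t a `deg_table`.
#' @return The labelled `deg_table`.
#' @export
classify_direction <- function(t) {
  stopifnot(inherits(t, "deg_table"))
  zero <- t$log2fc == 0
  if (any(zero)) {
    warning(sum(zero), " record(s) with log2fc == 0 excluded from ",
            "direction classification")
  }
  out <- t[!zero, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  attr(out, "label") <- attr(t, "label")
  attr(out, "n_zero_excluded") <- sum(zero)
  class(out) <- class(t)
  out
}

#' Cross-condition concordance of two DE tables
#'
#' Filters both tables at `alpha`, intersects on exact `gene_id`, counts
#' shared genes and direction-parallel genes (significant in both with the
#' same `log2fc` sign; zero fold changes excluded), and computes the
#' Pearson correlation of the two log2 fold-change vectors over the shared
#' genes.
#'
#' @param t1,t2 `deg_table` objects.
#' @param alpha significance threshold (default 0.05, strict `<`).
#' @return A list of class `overlap_result`: `n_sig_1`, `n_sig_2`,
#'   `n_shared`, `n_parallel`, `n_parallel_up`, `n_parallel_down`,
#'   `pearson_r` (`NA` with `r_missing_reason` when fewer than 3 shared
#'   genes), `n_used_for_r`, and the shared-gene data frame in `shared`.
#' @export
concordance <- function(t1, t2, alpha = 0.05) {
  s1 <- filter_significant(t1, alpha)
  s2 <- filter_significant(t2, alpha)
  shared_ids <- intersect(s1$gene_id, s2$gene_id)
  i1 <- match(shared_ids, s1$gene_id)
  i2 <- match(shared_ids, s2$gene_id)
  lfc1 <- s1$log2fc[i1]
  lfc2 <- s2$log2fc[i2]
  nonzero <- lfc1 != 0 & lfc2 != 0
  parallel_up <- nonzero & lfc1 > 0 & lfc2 > 0
  parallel_down <- nonzero & lfc1 < 0 & lfc2 < 0
  n_shared <- length(shared_ids)
  if (n_shared >= 3L) {
    r <- stats::cor(lfc1, lfc2, method = "pearson")
    reason <- NA_character_
  } else {
    r <- NA_real_
    reason <- sprintf("only %d shared significant gene(s); at least 3 needed",
                      n_shared)
  }
  shared <- data.frame(gene_id = shared_ids, log2fc_1 = lfc1, log2fc_2 = lfc2,
                       parallel = parallel_up | parallel_down,
                       stringsAsFactors = FALSE)
  structure(
    list(n_sig_1 = nrow(s1), n_sig_2 = nrow(s2), n_shared = n_shared,
         n_parallel = sum(parallel_up) + sum(parallel_down),
         n_parallel_up = sum(parallel_up),
         n_parallel_down = sum(parallel_down),
         pearson_r = r, n_used_for_r = if (is.na(r)) 0L else n_shared,
         r_missing_reason = reason,
         label_1 = attr(t1, "label"), label_2 = attr(t2, "label"),
         alpha = alpha, shared = shared),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> %s vs %s (padj < %g):\n  significant: %d / %d; shared: %d; parallel: %d (%d up, %d down)\n  Pearson r over shared log2FC: %s\n",
    x$label_1, x$label_2, x$alpha, x$n_sig_1, x$n_sig_2, x$n_shared,
    x$n_parallel, x$n_parallel_up, x$n_parallel_down,
    if (is.na(x$pearson_r)) paste0("NA (", x$r_missing_reason, ")")
    else sprintf("%.3f (n = %d)", x$pearson_r, x$n_used_for_r)))
  invisible(x)
}

#' Write an overlap result as JSON (and optionally the shared genes as CSV)
#'
#' @param x an `overlap_result`.
#' @param path output JSON path.
#' @param shared_csv optional path for the shared-gene CSV.
#' @return `path`, invisibly.
#' @export
write_overlap_json <- function(x, path, shared_csv = NULL) {
  stopifnot(inherits(x, "overlap_result"))
  out <- x[c("n_sig_1", "n_sig_2", "n_shared", "n_parallel",
             "n_parallel_up", "n_parallel_down", "pearson_r",
             "n_used_for_r", "r_missing_reason", "label_1", "label_2",
             "alpha")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  if (!is.null(shared_csv)) {
    utils::write.csv(x$shared, shared_csv, row.names = FALSE)
  }
  invisible(path)
}
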