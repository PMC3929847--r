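#' Read a p-value table
#'
#' Expects a TSV with header columns `test_id`, `gene_id`, `p`. Each row is
#' one test (e.g. one probe or one SNP) mapped to a gene.
#'
#' @param path file path.
#' @return data.frame with character `test_id`, `gene_id` and numeric `p`;
#'   validated so `p` is in `(0, 1]` and `test_id` is unique.
#' @export
read_pvalue_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("test_id", "gene_id", "p")
  if (!all(need %in% names(tab))) {
    stop("p-value table must have columns ", paste(need, collapse = ", "))
  }
  tab$p <- suppressWarnings(as.numeric(tab$p))
  bad <- which(!is.finite(tab$p) | tab$p <= 0 | tab$p > 1)
  if (length(bad) > 0) {
    stop("invalid p-value at data row ", bad[1],
         " (must be in (0, 1]): ", tab$p[bad[1]])
  }
  dup <- tab$test_id[duplicated(tab$test_id)]
  if (length(dup) > 0) {
    stop("duplicated test_id: ", paste(unique(dup), collapse = ", "))
  }
  tab[, need]
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated as
#' `set_id <TAB> description <TAB> member1 <TAB> member2 ...`.
#' Empty lines are skipped; duplicate members within a set are collapsed.
#'
#' @param path file path.
#' @return named list of character vectors (unique member gene ids), with
#'   a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) {
    warning("empty GMT file: ", path)
    return(structure(list(), descriptions = character(0)))
  }
  sets <- list()
  descr <- character(0)
  for (i in keep) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    }
    sets[[fields[1]]] <- unique(fields[-(1:2)])
    descr[fields[1]] <- fields[2]
  }
  structure(sets, descriptions = descr)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (a thin wrapper over [stats::p.adjust()] kept as
#' the pathway-mode surface).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Pathway analysis: combine per-test p-values over gene sets
#'
#' For every gene set: gather the p-values of tests whose gene is a member,
#' weight each test by its gene's test count (`n_i` = number of tests
#' mapping to gene `i`, the probe/SNP count) under the chosen scheme,
#' combine with [combine_pvalues()], and finally adjust the per-set
#' p-values across sets by Benjamini-Hochberg. Sets with no member genes
#' in the table are skipped with a warning.
#'
#' @param pvals data.frame from [read_pvalue_table()] (columns `test_id`,
#'   `gene_id`, `p`).
#' @param sets gene-set list from [read_gmt()].
#' @param weight_scheme `"inv_sqrt"`, `"inv"` or `"flat"`.
#' @param rho transformed-scale covariance matrix over the tests in
#'   `pvals` (rows/columns in table order or named by `test_id`), or
#'   `NULL` for the independence reference.
#' @param method which combined p-value to report per set (default the
#'   Satterthwaite-adjusted `"TA"`; with `rho = NULL` it equals the exact
#'   independence reference).
#' @param alpha significance threshold recorded in the output.
#' @return data.frame, one row per analyzed set: `set_id`, `n_genes`,
#'   `n_tests`, `statistic`, `p`, `p_adjusted`, `significant`; sorted by
#'   `p_adjusted`.
#' @export
run_pathway_analysis <- function(pvals, sets, weight_scheme = "inv",
                                 rho = NULL, method = "TA", alpha = 0.05) {
  if (inherits(rho, "cov_estimate")) rho <- rho$rho
  gene_counts <- table(pvals$gene_id)
  rows <- lapply(names(sets), function(sid) {
    members <- intersect(sets[[sid]], names(gene_counts))
    if (length(members) == 0) return(NULL)
    idx <- which(pvals$gene_id %in% members)
    n_i <- as.integer(gene_counts[pvals$gene_id[idx]])
    w <- weights_from_gene_sizes(n_i, weight_scheme)
    rho_sub <- if (!is.null(rho)) {
      if (!is.null(rownames(rho))) {
        rho[pvals$test_id[idx], pvals$test_id[idx], drop = FALSE]
      } else {
        rho[idx, idx, drop = FALSE]
      }
    } else NULL
    res <- combine_pvalues(pvals$p[idx], w, rho = rho_sub, methods = method)
    data.frame(set_id = sid, n_genes = length(members),
               n_tests = length(idx), statistic = res$statistic,
               p = unname(res$pvalues[method]))
  })
  skipped <- names(sets)[vapply(rows, is.null, logical(1))]
  if (length(skipped) > 0) {
    warning("skipping gene sets with no tests in the table: ",
            paste(skipped, collapse = ", "))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    stop("no gene set overlaps the p-value table")
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p)
  out$significant <- out$p_adjusted < alpha
  out[order(out$p_adjusted, out$p), ]
}

#' Write a numeric matrix as TSV (header = column names)
#'
#' Round-trip companion to [read_matrix_tsv()]; values are written with
#' full precision (15 significant digits).
#'
#' @param x matrix.
#' @param path output path.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- as.data.frame(signif(as.matrix(x), 15))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a numeric matrix from TSV (header row = column names)
#'
#' @param path input path.
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.delim(path, check.names = FALSE))
}
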