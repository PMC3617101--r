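#' Differential expression between case and control samples
#'
#' Computes a per-gene disease signature from a log2-scale expression matrix:
#' log2 fold change (mean case minus mean control), a two-sample p-value,
#' Benjamini-Hochberg FDR across all genes, and the DEG call at the standard
#' thresholds (linear fold change above `fc_threshold` in either direction and
#' FDR below `fdr_threshold`, both strict).
#'
#' The default test is Welch's two-sample t-test on the log2 values. The
#' `"moderated"` method delegates to limma's empirical-Bayes moderated t-test
#' instead; precomputed tables can also be supplied downstream, since every
#' consumer takes a plain signature tibble.
#'
#' @param expr A data frame whose first column is the gene identifier and
#'   remaining columns are per-sample log2 expression values.
#' @param groups A data frame with columns `sample` and `group`
#'   (`"case"`/`"control"`), or a character vector of groups named by sample.
#' @param method `"welch"` (default) or `"moderated"` (limma).
#' @param fc_threshold Linear fold-change threshold for the DEG call
#'   (default 1.5), applied two-sided: linear FC > 1.5 or < 1/1.5.
#' @param fdr_threshold FDR threshold for the DEG call (default 0.05).
#' @return A tibble with columns `gene`, `log2fc`, `pvalue`, `fdr`, `is_deg`.
#'   A gene constant across all samples gets p-value 1 by convention.
#' @examples
#' expr <- tibble::tibble(gene = c("g1", "g2"),
#'                        s1 = c(5, 7), s2 = c(5.1, 7.2),
#'                        s3 = c(7, 7.1), s4 = c(7.2, 6.9))
#' groups <- tibble::tibble(sample = c("s1", "s2", "s3", "s4"),
#'                          group = c("control", "control", "case", "case"))
#' differential_expression(expr, groups)
#' @export
differential_expression <- function(expr, groups,
                                    method = c("welch", "moderated"),
                                    fc_threshold = 1.5,
                                    fdr_threshold = 0.05) {
  method <- match.arg(method)
  expr <- as.data.frame(expr, check.names = FALSE)
  genes <- as.character(expr[[1L]])
  mat <- as.matrix(expr[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  grp <- normalize_groups(groups, colnames(mat))
  case <- mat[, grp == "case", drop = FALSE]
  ctrl <- mat[, grp == "control", drop = FALSE]
  if (ncol(case) < 2L || ncol(ctrl) < 2L) {
    abort("Each group needs at least 2 samples for the signature test.")
  }
  log2fc <- rowMeans(case) - rowMeans(ctrl)
  pvalue <- switch(method,
    welch = welch_pvalues(case, ctrl),
    moderated = moderated_pvalues(mat, grp)
  )
  # genes flat across every sample carry no evidence either way
  flat <- apply(mat, 1L, function(r) all(r == r[1L]))
  pvalue[flat] <- 1
  fdr <- stats::p.adjust(pvalue, method = "BH")
  sig <- tibble(gene = genes, log2fc = log2fc, pvalue = pvalue, fdr = fdr)
  sig$is_deg <- sig$gene %in% call_degs(sig, fc_threshold, fdr_threshold)
  sig
}

normalize_groups <- function(groups, samples) {
  if (is.data.frame(groups)) {
    grp <- setNames(as.character(groups$group), as.character(groups$sample))
  } else {
    grp <- setNames(as.character(groups), names(groups))
  }
  if (!all(samples %in% names(grp))) {
    abort("Every expression sample must be assigned a group.")
  }
  grp <- grp[samples]
  if (!all(grp %in% c("case", "control"))) {
    abort("Groups must be 'case' or 'control'.")
  }
  grp
}

# vectorized Welch t-test on rows; cross-checked against stats::t.test
welch_pvalues <- function(case, ctrl) {
  n1 <- ncol(case); n2 <- ncol(ctrl)
  v1 <- apply(case, 1L, var); v2 <- apply(ctrl, 1L, var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (rowMeans(case) - rowMeans(ctrl)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  # zero variance in both groups with equal means -> 0/0; no evidence
  p[!is.finite(tstat)] <- 1
  p
}

moderated_pvalues <- function(mat, grp) {
  if (!requireNamespace("limma", quietly = TRUE)) {
    abort("method = 'moderated' requires the limma package.")
  }
  design <- cbind(intercept = 1, case = as.integer(grp == "case"))
  fit <- limma::eBayes(limma::lmFit(mat, design))
  fit$p.value[, "case"]
}

#' Call differentially expressed genes from a signature table
#'
#' A gene is a DEG iff its linear fold change exceeds `fc_threshold` in either
#' direction (|log2fc| > log2(fc_threshold)) and its FDR is below
#' `fdr_threshold`; both comparisons are strict, so boundary values are
#' excluded.
#'
#' @param sig A signature tibble with columns `gene`, `log2fc`, `fdr`.
#' @param fc_threshold Linear fold-change threshold, default 1.5.
#' @param fdr_threshold FDR threshold, default 0.05.
#' @return Character vector of DEG gene identifiers.
#' @export
call_degs <- function(sig, fc_threshold = 1.5, fdr_threshold = 0.05) {
  if (fc_threshold <= 0 || fdr_threshold <= 0) {
    abort("Thresholds must be positive.")
  }
  keep <- abs(sig$log2fc) > log2(fc_threshold) & sig$fdr < fdr_threshold
  sig$gene[keep & !is.na(keep)]
}

#' Map a signature onto network nodes as a seed signal
#'
#' Produces the per-node weight vector that seeds all four prioritizers:
#' DEG-mapped nodes carry their fold change (by default the absolute log2
#' value, so ranking mass is non-negative), every other node carries 0. Genes
#' absent from the network are dropped with a message; if several genes map to
#' one node (complex nodes) the maximum weight wins.
#'
#' @param sig A signature tibble (see [differential_expression()]).
#' @param net An `interaction_network`.
#' @param id_map Optional data frame with columns `gene`, `node` translating
#'   gene ids to network node ids; defaults to the identity mapping.
#' @param fc_mode How the fold change becomes a weight: `"abs_log2"`
#'   (default), `"signed_log2"`, or `"linear"` (2^|log2fc|).
#' @param fc_threshold,fdr_threshold DEG thresholds, see [call_degs()].
#' @param quiet Suppress the dropped-gene message.
#' @return A tibble with columns `node`, `weight`, `is_deg` covering every
#'   network node. Errors if no DEG maps to the network: at least one
#'   differentially expressed gene is required to seed the methods.
#' @export
map_signature_to_network <- function(sig, net, id_map = NULL,
                                     fc_mode = c("abs_log2", "signed_log2",
                                                 "linear"),
                                     fc_threshold = 1.5,
                                     fdr_threshold = 0.05,
                                     quiet = FALSE) {
  fc_mode <- match.arg(fc_mode)
  stopifnot(inherits(net, "interaction_network"))
  degs <- call_degs(sig, fc_threshold, fdr_threshold)
  deg_sig <- sig[sig$gene %in% degs, , drop = FALSE]
  if (is.null(id_map)) {
    id_map <- tibble(gene = deg_sig$gene, node = deg_sig$gene)
  }
  mapped <- merge(deg_sig, as.data.frame(id_map), by = "gene")
  in_net <- mapped$node %in% net$nodes
  n_dropped <- sum(!in_net)
  if (n_dropped > 0L && !quiet) {
    message(sprintf("%d DEG(s) not present in the network were dropped.",
                    n_dropped))
  }
  mapped <- mapped[in_net, , drop = FALSE]
  if (nrow(mapped) == 0L) {
    abort(paste("No differentially expressed gene maps to the network;",
                "at least one DEG is required to seed the prioritizers."))
  }
  w <- switch(fc_mode,
    abs_log2 = abs(mapped$log2fc),
    signed_log2 = mapped$log2fc,
    linear = 2^abs(mapped$log2fc)
  )
  # many-to-one gene->node collisions: keep the maximum weight
  w_by_node <- tapply(w, mapped$node, max)
  weight <- setNames(numeric(length(net$nodes)), net$nodes)
  weight[names(w_by_node)] <- as.numeric(w_by_node)
  tibble(node = net$nodes, weight = unname(weight),
         is_deg = net$nodes %in% mapped$node)
}

#' Read / write signature tables
#' @param path TSV path with columns `gene`, `log2fc`, `pvalue`, `fdr`.
#' @return [read_signature()]: a signature tibble (with `is_deg` recomputed at
#'   the default thresholds if absent).
#' @export
read_signature <- function(path) {
  sig <- read_tsv_plain(path)
  needed <- c("gene", "log2fc", "pvalue", "fdr")
  if (!all(needed %in% names(sig))) {
    abort("Signature file must have columns gene, log2fc, pvalue, fdr.")
  }
  sig$gene <- as.character(sig$gene)
  if (!"is_deg" %in% names(sig)) {
    sig$is_deg <- sig$gene %in% call_degs(sig)
  }
  as_tibble(sig)
}

#' @rdname read_signature
#' @param sig A signature tibble.
#' @export
write_signature <- function(sig, path) write_tsv_plain(sig, path)
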