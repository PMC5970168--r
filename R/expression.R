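# Tissue expression z-scoring and qRT-PCR relative expression (Livak
# 2^-ddCt) with per-treatment induction calling.

#' Row-wise z-score normalization of an expression matrix
#'
#' Each gene row x is transformed to z = (x - mean(x)) / sd(x), with the
#' sample standard deviation (n - 1 divisor). Constant rows, where the
#' standard deviation vanishes, map to all zeros and are flagged in the
#' `constant_genes` attribute.
#'
#' @param mat Numeric matrix, genes in rows, tissues in columns (>= 2
#'   columns, no missing values, FPKM >= 0).
#' @return Matrix of the same shape; attribute `constant_genes` holds the
#'   row names (or indices) of degenerate rows.
#' @export
#' @examples
#' zscore_normalize(rbind(g1 = c(1, 2, 3)))
zscore_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("z-scoring requires at least 2 tissues")
  if (anyNA(mat)) stop("expression matrix contains missing values")
  if (any(mat < 0)) stop("expression matrix contains negative values")
  mu <- rowMeans(mat)
  sigma <- apply(mat, 1L, sd)
  constant <- sigma == 0
  sigma[constant] <- 1  # rows become exactly zero after centering
  z <- (mat - mu) / sigma
  flagged <- if (is.null(rownames(mat))) which(constant) else
    rownames(mat)[constant]
  if (any(constant))
    message(sum(constant), " constant expression row(s) mapped to zeros")
  structure(z, constant_genes = flagged)
}

#' Livak relative expression (2^-ddCt) between two replicate Ct cells
#'
#' dCt = ct_target - ct_reference per replicate; ddCt = mean dCt(treated)
#' - mean dCt(mock); returns the fold change E/C = 2^(-ddCt). Assumes
#' amplification efficiency 2 for both target and reference.
#'
#' @param treated,mock Data frames (or lists) with numeric `ct_target`
#'   and `ct_reference` replicate vectors.
#' @return Fold change (dimensionless E/C ratio).
#' @references Livak KJ, Schmittgen TD (2001) Methods 25:402-408.
#' @export
#' @examples
#' relative_expression(list(ct_target = 20, ct_reference = 15),
#'                     list(ct_target = 22, ct_reference = 15))  # 4
relative_expression <- function(treated, mock) {
  for (cell in list(treated, mock)) {
    if (is.null(cell$ct_target) || is.null(cell$ct_reference) ||
        anyNA(cell$ct_target) || anyNA(cell$ct_reference))
      stop("both arms need complete ct_target and ct_reference values")
  }
  d_ct_t <- mean(treated$ct_target - treated$ct_reference)
  d_ct_m <- mean(mock$ct_target - mock$ct_reference)
  2^(-(d_ct_t - d_ct_m))
}

#' Call stress induction from a qRT-PCR time course
#'
#' At each time point the treated and mock arms are compared: the fold
#' change comes from [relative_expression()] and the p-value from a
#' two-sided pooled-variance Student's t-test on the replicate dCt
#' values. A gene is called `up` if any time point has fold >=
#' `fold_threshold` with p < `alpha1`, and `down` (the "D" code) if any
#' time point has fold <= 1/`fold_threshold` with p < `alpha1`; `up`
#' takes precedence if both fire. The peak time is the time of maximal
#' (up) or minimal (down) fold change, ties broken by the earliest time;
#' significance is reported as `p<0.01` when the peak time point reaches
#' p < `alpha2`, else `p<0.05`.
#'
#' @param course Data frame with columns `gene`, `treatment`, `time_h`,
#'   `arm` (`treated`/`mock`), `replicate`, `ct_target`, `ct_reference`.
#'   Both arms must be present at every time point with >= 2 replicates.
#' @param alpha1,alpha2 Significance thresholds (defaults 0.05 and 0.01).
#' @param fold_threshold Fold-change threshold (default 2).
#' @return One-row data frame: `gene`, `treatment`, `status`
#'   (up/down/none), `significance` (`p<0.01`/`p<0.05`/`ns`),
#'   `max_fold_change` (extreme E/C in the called direction),
#'   `peak_time_h` (NA when status is none).
#' @export
call_induction <- function(course, alpha1 = 0.05, alpha2 = 0.01,
                           fold_threshold = 2.0) {
  need <- c("gene", "treatment", "time_h", "arm", "replicate",
            "ct_target", "ct_reference")
  missing_cols <- setdiff(need, names(course))
  if (length(missing_cols))
    stop("time course lacks column(s): ", paste(missing_cols, collapse = ", "))
  gene <- unique(as.character(course$gene))
  treatment <- unique(as.character(course$treatment))
  if (length(gene) != 1L || length(treatment) != 1L)
    stop("call_induction expects one gene x treatment time course")
  times <- sort(unique(course$time_h))
  per_tp <- lapply(times, function(tp) {
    tr <- course[course$time_h == tp & course$arm == "treated", ]
    mo <- course[course$time_h == tp & course$arm == "mock", ]
    if (nrow(tr) < 2L || nrow(mo) < 2L)
      stop("fewer than 2 replicates at time ", tp, " h for ", gene,
           "/", treatment)
    d_tr <- tr$ct_target - tr$ct_reference
    d_mo <- mo$ct_target - mo$ct_reference
    p <- if (sd(c(d_tr, d_mo)) == 0) 1 else
      t.test(d_tr, d_mo, var.equal = TRUE)$p.value
    c(fold = 2^(-(mean(d_tr) - mean(d_mo))), p = p)
  })
  fold <- vapply(per_tp, `[[`, numeric(1L), "fold")
  pval <- vapply(per_tp, `[[`, numeric(1L), "p")

  up_hit <- fold >= fold_threshold & pval < alpha1
  down_hit <- fold <= 1 / fold_threshold & pval < alpha1
  if (any(up_hit)) {
    status <- "up"
    peak <- times[which.max(fold)]  # which.max takes the earliest tie
    max_fold <- max(fold)
  } else if (any(down_hit)) {
    status <- "down"
    peak <- times[which.min(fold)]
    max_fold <- min(fold)
  } else {
    status <- "none"
    peak <- NA_real_
    max_fold <- fold[which.max(abs(log2(fold)))]
  }
  significance <- if (status == "none") "ns"
  else if (pval[match(peak, times)] < alpha2) "p<0.01" else "p<0.05"
  data.frame(gene = gene, treatment = treatment, status = status,
             significance = significance, max_fold_change = max_fold,
             peak_time_h = peak, stringsAsFactors = FALSE)
}

#' Induction calls for every gene x treatment course in a Ct table
#'
#' @param ct_table Long-format Ct table covering one or more gene x
#'   treatment time courses (columns as in [call_induction()]).
#' @inheritParams call_induction
#' @return Data frame of calls, one row per gene x treatment.
#' @export
call_inductions <- function(ct_table, alpha1 = 0.05, alpha2 = 0.01,
                            fold_threshold = 2.0) {
  key <- interaction(ct_table$gene, ct_table$treatment, drop = TRUE)
  out <- do.call(rbind, lapply(split(ct_table, key), call_induction,
                               alpha1 = alpha1, alpha2 = alpha2,
                               fold_threshold = fold_threshold))
  rownames(out) <- NULL
  out[gene_order(out$gene, out$treatment), , drop = FALSE]
}

#' Summarize induction calls into a gene x treatment status table
#'
#' Builds the status matrix with the published legend codes: `**` (up,
#' p < 0.01), `*` (up, p < 0.05), `D` (significant reduction), `-` (no
#' detected difference), plus per-treatment counts of up-called genes
#' and per-gene counts of treatments with an up call.
#'
#' @param calls Data frame of calls from [call_inductions()].
#' @return List with `status` (gene x treatment character matrix),
#'   `up_per_treatment` (named integer vector) and `up_per_gene`.
#' @export
induction_matrix <- function(calls) {
  if (nrow(calls) == 0L) {
    return(list(status = matrix(character(), 0L, 0L),
                up_per_treatment = integer(), up_per_gene = integer()))
  }
  if (anyDuplicated(calls[c("gene", "treatment")]))
    stop("duplicate (gene, treatment) induction calls")
  genes <- unique(calls$gene)[gene_order(unique(calls$gene))]
  treatments <- intersect(ALL_TREATMENTS, unique(calls$treatment))
  treatments <- c(treatments, setdiff(unique(calls$treatment), treatments))
  status <- matrix("-", length(genes), length(treatments),
                   dimnames = list(genes, treatments))
  code <- ifelse(calls$status == "up",
                 ifelse(calls$significance == "p<0.01", "**", "*"),
                 ifelse(calls$status == "down", "D", "-"))
  status[cbind(match(calls$gene, genes),
               match(calls$treatment, treatments))] <- code
  up <- calls$status == "up"
  list(status = status,
       up_per_treatment = vapply(treatments, function(tr)
         sum(up & calls$treatment == tr), integer(1L)),
       up_per_gene = vapply(genes, function(g)
         sum(up & calls$gene == g), integer(1L)))
}
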