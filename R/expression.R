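# Residual sum of squares of every gene against a fixed design matrix,
# computed once per design via the QR decomposition (the per-gene ANOVAs all
# share one design, so the projections are shared too).
rssAll <- function(Y, X) {
  qrx <- qr(X)
  q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
  list(rss = pmax(colSums(Y^2) - colSums(crossprod(q, Y)^2), 0),
       rank = qrx$rank)
}

# F-test of a nested model comparison with a common denominator (the fullest
# model's mean squared error).  Degenerate genes (zero residual and zero
# effect variance) get p = 1.
nestedF <- function(rss_reduced, rss_full, df_num, mse, df_den) {
  num <- (rss_reduced - rss_full) / df_num
  p <- stats::pf(num / mse, df_num, df_den, lower.tail = FALSE)
  p[mse <= 0 & num <= 1e-12] <- 1
  p[mse <= 0 & num > 1e-12] <- 0
  p
}

checkDesign <- function(mat, design) {
  need <- c("sample", "allele", "noncoding_origin", "coding_origin", "time",
            "biorep", "tech_rep")
  if (!all(need %in% names(design)))
    stop("design must have columns: ", paste(need, collapse = ", "))
  if (ncol(mat) != nrow(design))
    stop("matrix columns (", ncol(mat), ") != design rows (", nrow(design),
         ")")
  cells <- table(design$allele, design$time)
  if (any(cells < 2))
    stop("every (allele, time) cell needs >= 2 replicates")
  invisible(design)
}

# First-level per-gene p-values: allele main effect, allele x time
# interaction, and time main effect, with technical replicate as a blocking
# term and a single error term from the full model.
firstLevelPvalues <- function(mat, design) {
  Y <- t(mat)
  al <- factor(design$allele)
  tm <- factor(design$time)
  tech <- factor(design$tech_rep)
  n <- nrow(Y)
  mFull <- rssAll(Y, stats::model.matrix(~ al * tm + tech))
  mNoInt <- rssAll(Y, stats::model.matrix(~ al + tm + tech))
  mNoAl <- rssAll(Y, stats::model.matrix(~ tm + tech))
  mNoTm <- rssAll(Y, stats::model.matrix(~ al + tech))
  df_den <- n - mFull$rank
  mse <- mFull$rss / df_den
  list(
    p_allele = nestedF(mNoAl$rss, mNoInt$rss, mNoInt$rank - mNoAl$rank,
                       mse, df_den),
    p_allele_time = nestedF(mNoInt$rss, mFull$rss,
                            mFull$rank - mNoInt$rank, mse, df_den),
    p_time = nestedF(mNoTm$rss, mNoInt$rss, mNoInt$rank - mNoTm$rank,
                     mse, df_den))
}

# Source p-values (coding / noncoding / interaction) for a set of genes from
# a response matrix U (units x genes) and unit-level origin indicators.
sourcePvalues <- function(U, nc, cd) {
  nc <- factor(nc)
  cd <- factor(cd)
  mFull <- rssAll(U, stats::model.matrix(~ nc * cd))
  mAdd <- rssAll(U, stats::model.matrix(~ nc + cd))
  mN <- rssAll(U, stats::model.matrix(~ nc))
  mC <- rssAll(U, stats::model.matrix(~ cd))
  df_den <- nrow(U) - mFull$rank
  mse <- mFull$rss / df_den
  list(
    p_coding = nestedF(mN$rss, mAdd$rss, mAdd$rank - mN$rank, mse, df_den),
    p_noncoding = nestedF(mC$rss, mAdd$rss, mAdd$rank - mC$rank, mse,
                          df_den),
    p_cn_interaction = nestedF(mAdd$rss, mFull$rss, mFull$rank - mAdd$rank,
                               mse, df_den))
}

#' Per-gene expression ANOVA with effect-source classification
#'
#' First level: for every gene, `expression = allele*time + technical
#' replicate + error`, testing the allele main effect and the allele-by-time
#' interaction (plus the sulfite-treatment time effect).  Second level: for
#' genes with a significant allele main effect, the allele factor is
#' decomposed as `expression = noncoding*coding + error` on the sample
#' values; for genes whose allele effect varies by time, the same
#' decomposition is fitted to the per-culture sulfite response (time-point
#' difference averaged over technical replicates).  Each significant gene is
#' classified by the smallest significant source p-value as "coding",
#' "noncoding" or "interaction".
#'
#' Genes with missing values are flagged (`flagged = TRUE`, p-values NA),
#' never silently dropped.
#'
#' @param mat genes x samples matrix of log2 expression values (rownames =
#'   gene ids), typically after [medianNormalize()]
#' @param design data.frame describing the columns of `mat`: `sample`,
#'   `allele`, `noncoding_origin`, `coding_origin`, `time`, `biorep`,
#'   `tech_rep`
#' @param p_threshold significance level used both to build the second-level
#'   gene universe and to classify sources (default 0.01)
#' @return data.frame with one row per gene: first-level p-values,
#'   `log2fc_sulfite`, source p-values, `source_class`, `flagged`
#' @export
geneAnova <- function(mat, design, p_threshold = 0.01) {
  checkDesign(mat, design)
  genes <- rownames(mat) %||% paste0("g", seq_len(nrow(mat)))
  flagged <- apply(mat, 1, anyNA)
  res <- data.frame(gene = genes, p_allele = NA_real_,
                    p_allele_time = NA_real_, p_time = NA_real_,
                    log2fc_sulfite = NA_real_, p_coding = NA_real_,
                    p_noncoding = NA_real_, p_cn_interaction = NA_real_,
                    source_class = NA_character_, flagged = flagged,
                    stringsAsFactors = FALSE)
  okm <- mat[!flagged, , drop = FALSE]
  if (nrow(okm) == 0) return(res)
  p1 <- firstLevelPvalues(okm, design)
  res$p_allele[!flagged] <- p1$p_allele
  res$p_allele_time[!flagged] <- p1$p_allele_time
  res$p_time[!flagged] <- p1$p_time
  res$log2fc_sulfite[!flagged] <-
    colMeans(t(okm)[design$time == max(design$time), , drop = FALSE]) -
    colMeans(t(okm)[design$time == min(design$time), , drop = FALSE])

  # second level on the significant universe
  idx <- which(!flagged)
  sig_main <- idx[p1$p_allele < p_threshold]
  sig_int <- idx[p1$p_allele_time < p_threshold]
  if (length(sig_main)) {
    sp <- sourcePvalues(t(mat[sig_main, , drop = FALSE]),
                        design$noncoding_origin, design$coding_origin)
    res$p_coding[sig_main] <- sp$p_coding
    res$p_noncoding[sig_main] <- sp$p_noncoding
    res$p_cn_interaction[sig_main] <- sp$p_cn_interaction
  }
  only_int <- setdiff(sig_int, sig_main)
  if (length(only_int)) {
    # per-culture sulfite response: t_late - t_early, technical reps averaged
    unit <- interaction(design$allele, design$biorep, drop = TRUE)
    t_hi <- design$time == max(design$time)
    U <- vapply(levels(unit), function(u) {
      i <- unit == u
      colMeans(t(mat[only_int, i & t_hi, drop = FALSE])) -
        colMeans(t(mat[only_int, i & !t_hi, drop = FALSE]))
    }, numeric(length(only_int)))
    U <- if (length(only_int) == 1) matrix(U, nrow = 1) else U
    meta <- design[!duplicated(unit), ]
    meta <- meta[match(levels(unit), unit[!duplicated(unit)]), ]
    sp <- sourcePvalues(t(U), meta$noncoding_origin, meta$coding_origin)
    res$p_coding[only_int] <- sp$p_coding
    res$p_noncoding[only_int] <- sp$p_noncoding
    res$p_cn_interaction[only_int] <- sp$p_cn_interaction
  }
  src <- c("p_coding", "p_noncoding", "p_cn_interaction")
  lab <- c("coding", "noncoding", "interaction")
  for (i in union(sig_main, sig_int)) {
    ps <- unlist(res[i, src])
    if (all(is.na(ps))) next
    res$source_class[i] <- if (min(ps, na.rm = TRUE) < p_threshold)
      lab[which.min(ps)] else "none"
  }
  res
}

#' Median normalization of expression arrays
#'
#' Subtracts each array's median log-intensity so that every array has
#' median zero; rank order within an array is preserved.  Idempotent.
#'
#' @param mat genes x arrays matrix of log-scale values
#' @return normalized matrix
#' @export
medianNormalize <- function(mat) {
  meds <- apply(mat, 2, stats::median, na.rm = TRUE)
  if (any(is.na(meds))) stop("array with no non-missing values")
  sweep(mat, 2, meds)
}

#' Permutation-based false discovery rate
#'
#' Permutes biological sample labels and recomputes the number of genes
#' significant at `alpha`, estimating FDR = mean permuted count / observed
#' count.  The permutation unit is the biological sample (technical
#' replicates travel together).  For the allele main-effect test, allele
#' labels are permuted within each time point (preserving the time
#' structure); for the allele-by-time interaction test they are permuted
#' across all units.  Deterministic given `seed`.
#'
#' @param mat genes x samples matrix (log2)
#' @param design as in [geneAnova()]
#' @param alpha per-test significance threshold (default 0.01)
#' @param nperm number of label permutations, >= 20 (default 100)
#' @param seed RNG seed
#' @param test "allele" or "interaction"
#' @return list: `alpha`, `test`, `n_observed`, `mean_null`, `fdr` (NA with
#'   a note when nothing is observed significant), `null_counts`
#' @export
permutationFdr <- function(mat, design, alpha = 0.01, nperm = 100, seed = 1,
                           test = c("allele", "interaction")) {
  test <- match.arg(test)
  if (nperm < 20) stop("nperm must be >= 20")
  checkDesign(mat, design)
  ok <- !apply(mat, 1, anyNA)
  m <- mat[ok, , drop = FALSE]
  pcol <- if (test == "allele") "p_allele" else "p_allele_time"
  countSig <- function(d) sum(firstLevelPvalues(m, d)[[pcol]] < alpha)
  n_obs <- countSig(design)
  unit <- interaction(design$allele, design$biorep, design$time, drop = TRUE)
  uidx <- which(!duplicated(unit))
  umeta <- design[uidx, ]
  null_counts <- withSeed(deriveSeed(seed, 211L), {
    vapply(seq_len(nperm), function(b) {
      new_allele <- umeta$allele
      if (test == "allele") {
        for (tp in unique(umeta$time)) {
          i <- which(umeta$time == tp)
          new_allele[i] <- new_allele[sample(i)]
        }
      } else {
        new_allele <- new_allele[sample(length(new_allele))]
      }
      d <- design
      d$allele <- new_allele[match(unit, unit[uidx])]
      countSig(d)
    }, numeric(1))
  })
  mean_null <- mean(null_counts)
  list(alpha = alpha, test = test, n_observed = n_obs,
       mean_null = mean_null,
       fdr = if (n_obs > 0) mean_null / n_obs else NA_real_,
       note = if (n_obs == 0) "no observed significant genes; FDR undefined"
              else "", null_counts = null_counts)
}

#' Fold-change gene sets after sulfite treatment
#'
#' Genes with a strictly greater than `fc_threshold`-fold change between the
#' two time points and a significant treatment (time) effect, split into
#' disjoint up- and down-regulated sets.  The inequality is strict: a gene at
#' exactly the threshold is excluded.
#'
#' @param results data.frame from [geneAnova()]
#' @param fc_threshold fold-change cutoff on the natural scale (default 2)
#' @param p_threshold significance cutoff on the time effect (default 0.01)
#' @return list with character vectors `up` and `down`
#' @export
foldChangeSets <- function(results, fc_threshold = 2, p_threshold = 0.01) {
  lfc <- results$log2fc_sulfite
  p <- results$p_time
  ok <- !is.na(lfc) & !is.na(p) & p < p_threshold
  list(up = results$gene[ok & lfc > log2(fc_threshold)],
       down = results$gene[ok & lfc < -log2(fc_threshold)])
}

#' Plate-corrected relative expression from qPCR Ct values
#'
#' Relative expression is 2^-(Ct_target - Ct_reference) (reference gene
#' ACT1, amplification efficiency 2).  For allele-specific primer assays, a
#' plate-specific correction factor is estimated from measurements of
#' genomic DNA of a heterozygous strain carrying both alleles: since the
#' true allele ratio in that DNA is 1:1, the heterozygote's apparent
#' per-primer expression (rescaled by the plate's geometric mean across
#' primers) is pure primer/PCR-efficiency bias, and each sample measurement
#' is divided by it.  After correction the heterozygote's allele ratio is
#' exactly 1.  Values are then mean-normalized for day and batch effects on
#' the log2 scale.
#'
#' @param records data.frame with columns `sample`, `gene`, `primer`
#'   (allele-specific primer label, NA for ordinary assays), `ct_target`,
#'   `ct_reference`, `plate`, `day`, `batch`
#' @param het_calibration data.frame with columns `plate`, `primer`,
#'   `ct_target`, `ct_reference` measured on heterozygous genomic DNA; one
#'   row per (plate, primer) used by any allele-specific record
#' @return `records` with added columns `rel_expr` (corrected, un-normalized)
#'   and `rel_expr_norm` (day/batch mean-normalized)
#' @export
plateCorrectedRelativeExpression <- function(records, het_calibration = NULL) {
  need <- c("sample", "gene", "ct_target", "ct_reference", "plate")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (anyNA(records$ct_reference))
    stop("missing reference (ACT1) Ct value")
  if (anyNA(records$ct_target)) stop("missing target Ct value")
  if (any(records$ct_target <= 0) || any(records$ct_reference <= 0))
    stop("Ct values must be positive")
  rel <- 2^(-(records$ct_target - records$ct_reference))
  primer <- records$primer %||% rep(NA_character_, nrow(records))
  asp <- !is.na(primer)
  if (any(asp)) {
    if (is.null(het_calibration))
      stop("allele-specific records present but no heterozygote calibration")
    cal <- het_calibration
    cal$rel <- 2^(-(cal$ct_target - cal$ct_reference))
    for (pl in unique(records$plate[asp])) {
      sub <- cal[cal$plate == pl, ]
      prs <- unique(primer[asp & records$plate == pl])
      if (!all(prs %in% sub$primer))
        stop("missing heterozygote calibration for plate ", pl)
      gm <- exp(mean(log(sub$rel)))
      for (pr in prs) {
        fac <- sub$rel[sub$primer == pr][1] / gm
        i <- asp & records$plate == pl & primer == pr
        rel[i] <- rel[i] / fac
      }
    }
  }
  records$rel_expr <- rel
  lg <- log2(rel)
  for (v in c("day", "batch")) {
    if (!v %in% names(records)) next
    for (g in unique(records[[v]]))
      lg[records[[v]] == g] <- lg[records[[v]] == g] -
        mean(lg[records[[v]] == g])
  }
  records$rel_expr_norm <- 2^lg
  records
}
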