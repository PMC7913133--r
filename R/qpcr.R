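#' Read or validate a replicate-structured Ct table
#'
#' The expected layout is one row per well: columns `gene`, `group`,
#' `bio_rep`, `tech_rep`, `ct`. Ct values must be finite; the reference
#' gene must be measured in every group.
#'
#' @param x a CSV path or a data frame in the layout above.
#' @param reference_gene normalizer transcript (default `"actin-2"`).
#' @return validated data frame with attribute `reference_gene`.
#' @export
ct_table <- function(x, reference_gene = "actin-2") {
  tab <- if (is.character(x)) {
    utils::read.csv(x, stringsAsFactors = FALSE)
  } else {
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  need <- c("gene", "group", "bio_rep", "tech_rep", "ct")
  if (!all(need %in% names(tab))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  }
  tab$ct <- as.numeric(tab$ct)
  if (any(!is.finite(tab$ct))) stop("non-finite Ct value(s)")
  for (g in unique(tab$group)) {
    if (!reference_gene %in% tab$gene[tab$group == g]) {
      stop("reference gene '", reference_gene,
           "' is missing from group '", g, "'")
    }
  }
  attr(tab, "reference_gene") <- reference_gene
  tab
}

#' Average technical replicates
#'
#' Arithmetic mean Ct per (gene, group, biological replicate); biological
#' replicates remain the units of analysis downstream.
#'
#' @param tab a [ct_table()] (or compatible data frame).
#' @return data frame `gene`, `group`, `bio_rep`, `ct`.
#' @export
collapse_technical <- function(tab) {
  out <- aggregate(ct ~ gene + group + bio_rep, data = tab, FUN = mean)
  out <- out[order(out$gene, out$group, out$bio_rep), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-biological-replicate delta-Ct (target minus reference) for one gene
# in one group; errors if the design is not matched per replicate.
delta_ct <- function(collapsed, gene, group, reference_gene) {
  tg <- collapsed[collapsed$gene == gene & collapsed$group == group, ]
  rf <- collapsed[collapsed$gene == reference_gene &
                  collapsed$group == group, ]
  if (nrow(rf) == 0L) {
    stop("reference gene '", reference_gene, "' missing from group '",
         group, "'")
  }
  if (nrow(tg) == 0L) {
    stop("gene '", gene, "' missing from group '", group, "'")
  }
  reps <- intersect(tg$bio_rep, rf$bio_rep)
  if (length(reps) == 0L) stop("no shared biological replicates")
  tg$ct[match(reps, tg$bio_rep)] - rf$ct[match(reps, rf$bio_rep)]
}

#' Comparative-Ct (delta-delta-Ct) relative expression
#'
#' After averaging technical replicates, the gene's Ct is normalized to the
#' reference gene per group (delta-Ct), the treatment and control
#' delta-Cts are contrasted (delta-delta-Ct), and the fold change is
#' `efficiency^(-ddct)`.
#'
#' @param tab a [ct_table()].
#' @param gene target gene.
#' @param treatment_group,control_group group labels.
#' @param reference_gene normalizer (default from the table attribute,
#'   falling back to `"actin-2"`).
#' @param efficiency amplification efficiency as fold per cycle (2 =
#'   perfect doubling).
#' @return list with `gene`, `ddct` (cycles), `ratio` (fold change),
#'   `dct_treatment`, `dct_control` (per-replicate vectors).
#' @export
ddct_ratio <- function(tab, gene, treatment_group, control_group,
                       reference_gene = NULL, efficiency = 2) {
  stopifnot(efficiency > 1)
  if (is.null(reference_gene)) {
    reference_gene <- attr(tab, "reference_gene")
    if (is.null(reference_gene)) reference_gene <- "actin-2"
  }
  collapsed <- collapse_technical(tab)
  dct_t <- delta_ct(collapsed, gene, treatment_group, reference_gene)
  dct_c <- delta_ct(collapsed, gene, control_group, reference_gene)
  ddct <- mean(dct_t) - mean(dct_c)
  list(gene = gene, ddct = ddct, ratio = efficiency^(-ddct),
       dct_treatment = dct_t, dct_control = dct_c)
}

#' Randomization test for differential expression
#'
#' Fixed-reallocation randomization in the style of the REST software:
#' biological replicates (each carrying its target-and-reference delta-Ct)
#' are reshuffled between the two groups; the two-sided p-value is the
#' add-one-corrected fraction of permutations whose |delta-delta-Ct|
#' reaches the observed one: `p = (1 + #{|ddct*| >= |ddct|}) / (1 + B)`.
#'
#' @inheritParams ddct_ratio
#' @param n_permutations number of random reallocations.
#' @param seed integer seed (the test is deterministic given the seed).
#' @return list with `p_value`, `ddct`, `n_permutations`, `seed`.
#' @export
randomization_test <- function(tab, gene, treatment_group, control_group,
                               reference_gene = NULL, efficiency = 2,
                               n_permutations = 2000L, seed = 1L) {
  est <- ddct_ratio(tab, gene, treatment_group, control_group,
                    reference_gene, efficiency)
  x <- est$dct_treatment
  y <- est$dct_control
  if (length(x) < 2L || length(y) < 2L) {
    stop("randomization test needs >= 2 biological replicates per group")
  }
  pool <- c(x, y)
  nt <- length(x)
  obs <- abs(est$ddct)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  perm <- replicate(n_permutations, {
    idx <- sample.int(length(pool), nt)
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  p <- (1 + sum(perm >= obs - 1e-12)) / (1 + n_permutations)
  list(p_value = p, ddct = est$ddct, n_permutations = n_permutations,
       seed = seed)
}

#' Percentile bootstrap interval for the fold change
#'
#' Biological replicates are resampled with replacement within each group;
#' the interval is the percentile interval of the resampled
#' `efficiency^(-ddct*)`.
#'
#' @inheritParams randomization_test
#' @param n_boot bootstrap resamples.
#' @param level interval level.
#' @return list with `ci_low`, `ci_high`, `level`, `n_boot`.
#' @export
ddct_bootstrap_ci <- function(tab, gene, treatment_group, control_group,
                              reference_gene = NULL, efficiency = 2,
                              n_boot = 2000L, level = 0.95, seed = 1L) {
  est <- ddct_ratio(tab, gene, treatment_group, control_group,
                    reference_gene, efficiency)
  x <- est$dct_treatment
  y <- est$dct_control
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  boots <- replicate(n_boot, {
    dd <- mean(sample(x, replace = TRUE)) - mean(sample(y, replace = TRUE))
    efficiency^(-dd)
  })
  qs <- unname(quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2)))
  list(ci_low = qs[1], ci_high = qs[2], level = level, n_boot = n_boot)
}

#' Full delta-delta-Ct analysis of one gene
#'
#' Point estimate, randomization p-value and bootstrap interval in one
#' record.
#'
#' @inheritParams randomization_test
#' @param n_boot bootstrap resamples for the interval.
#' @param ci_level interval level.
#' @return one-row data frame: `gene`, `ddct`, `ratio`, `p_value`,
#'   `ci_low`, `ci_high`, `n_permutations`, `seed`.
#' @export
ddct_analysis <- function(tab, gene, treatment_group, control_group,
                          reference_gene = NULL, efficiency = 2,
                          n_permutations = 2000L, n_boot = 2000L,
                          ci_level = 0.95, seed = 1L) {
  est <- ddct_ratio(tab, gene, treatment_group, control_group,
                    reference_gene, efficiency)
  rt <- randomization_test(tab, gene, treatment_group, control_group,
                           reference_gene, efficiency, n_permutations, seed)
  ci <- ddct_bootstrap_ci(tab, gene, treatment_group, control_group,
                          reference_gene, efficiency, n_boot, ci_level,
                          seed + 1L)
  data.frame(gene = gene, ddct = est$ddct, ratio = est$ratio,
             p_value = rt$p_value, ci_low = ci$ci_low, ci_high = ci$ci_high,
             n_permutations = n_permutations, seed = seed,
             stringsAsFactors = FALSE)
}
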