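# Summary quantities: transduction efficiency, spread fraction, control
# normalization, region-split recipient counts, section-size QC, delta-delta-Ct
# relative expression, and the group comparisons used on those metrics.

#' Spread metrics from classified cells
#'
#' Transduction efficiency = donors / (donors + recipients + untransduced);
#' spread fraction = recipients / (recipients + untransduced), i.e.
#' recipients over the eGFP-negative gated population. AMBIGUOUS cells are
#' excluded from both denominators and reported. Cells left UNSET (e.g.
#' mCherry-negative in brain sections) are outside the gated population.
#'
#' @param records classified cell-records data frame.
#' @param condition optional condition label carried into the output.
#' @return one-row data frame of class \code{spread_metrics}: \code{n_gated},
#'   \code{n_donor}, \code{n_recipient}, \code{n_untransduced},
#'   \code{n_ambiguous}, \code{transduction_efficiency},
#'   \code{spread_fraction}, \code{condition}.
#' @export
compute_spread_metrics <- function(records, condition = NA_character_) {
  cl <- records$class_label
  if (is.null(cl)) stop("records are not classified")
  gated <- cl[cl != "UNSET"]
  if (length(gated) == 0) stop("zero gated cells")
  nd <- sum(gated == "DONOR")
  nr <- sum(gated == "RECIPIENT")
  nu <- sum(gated == "UNTRANSDUCED")
  na_ <- sum(gated == "AMBIGUOUS")
  te <- if (nd + nr + nu > 0) nd / (nd + nr + nu) else NA_real_
  sf <- if (nr + nu > 0) nr / (nr + nu) else NA_real_
  out <- data.frame(n_gated = length(gated), n_donor = nd, n_recipient = nr,
                    n_untransduced = nu, n_ambiguous = na_,
                    transduction_efficiency = te, spread_fraction = sf,
                    condition = condition, stringsAsFactors = FALSE)
  class(out) <- c("spread_metrics", class(out))
  out
}

#' Normalize replicate metrics to the control-group mean
#'
#' Divides every value by the mean of the control replicates, so the control
#' group's normalized mean is exactly 1.
#'
#' @param values numeric vector of per-replicate metrics.
#' @param control_values numeric vector of control replicates.
#' @return normalized values.
#' @export
normalize_to_control <- function(values, control_values) {
  if (length(control_values) == 0) stop("control values are empty")
  m <- mean(control_values)
  if (!is.finite(m) || m == 0) stop("control mean must be finite and non-zero")
  values / m
}

#' Count recipients per brain region, with section-size QC
#'
#' Each recipient is assigned to the region containing its centroid;
#' whole-brain = cortical + subcortical; centroids outside the section
#' footprint are counted as \code{NONE} and reported. Section area (mm^2)
#' is the footprint pixel count times the squared pixel size — reported as a
#' comparability check, not used as a divisor.
#'
#' @param records classified cell-records with centroids.
#' @param region a \code{\link{region_mask}}.
#' @return list: \code{counts} (data frame with cortical, subcortical, none,
#'   whole_brain recipient counts), \code{section_area_mm2}.
#' @export
count_recipients_by_region <- function(records, region) {
  stopifnot(inherits(region, "region_mask"))
  rec <- records[records$class_label == "RECIPIENT", , drop = FALSE]
  r <- round(rec$centroid_row); c <- round(rec$centroid_col)
  sh <- dim(region$regions)
  inside <- r >= 1 & r <= sh[1] & c >= 1 & c <= sh[2]
  regv <- rep(0L, nrow(rec))
  regv[inside] <- region$regions[cbind(r[inside], c[inside])]
  counts <- data.frame(
    cortical = sum(regv == 1L),
    subcortical = sum(regv == 2L),
    none = sum(regv == 0L)
  )
  counts$whole_brain <- counts$cortical + counts$subcortical
  list(counts = counts, section_area_mm2 = section_area_mm2(region))
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, dCt = Ct(target) - Ct(reference); ddCt = dCt - mean dCt of
#' the control group; relative expression = 2^(-ddCt). The control group's
#' geometric mean is 1 by construction.
#'
#' @param table data frame with columns \code{ct_target}, \code{ct_reference},
#'   \code{group} (containing at least one \code{"CONTROL"} row), and
#'   optionally \code{replicate}.
#' @return \code{table} with added \code{dct}, \code{ddct},
#'   \code{rel_expression}.
#' @export
delta_delta_ct <- function(table) {
  need <- c("ct_target", "ct_reference", "group")
  if (!all(need %in% names(table))) {
    stop("CT table needs columns: ", paste(need, collapse = ", "))
  }
  ct <- c(table$ct_target, table$ct_reference)
  if (any(!is.finite(ct)) || any(ct <= 0)) stop("CT values must be finite and > 0")
  if (!any(table$group == "CONTROL")) stop("CT table has no CONTROL rows")
  table$dct <- table$ct_target - table$ct_reference
  ref <- mean(table$dct[table$group == "CONTROL"])
  table$ddct <- table$dct - ref
  table$rel_expression <- 2^(-table$ddct)
  table
}

#' Compare metric values across conditions
#'
#' Two-group design: two-tailed two-sample Student t-test. Multi-group:
#' one-way ANOVA with Tukey HSD post-hoc pairwise comparisons.
#'
#' @param groups named list of numeric vectors (>= 2 values each).
#' @param design \code{"TWO_GROUP"} or \code{"MULTI_GROUP"}.
#' @param var_equal logical; pooled-variance t-test (default TRUE, the
#'   classic two-sample test).
#' @return list with \code{method}, \code{statistic} (t or F), \code{df},
#'   \code{p_value}, and for MULTI_GROUP a \code{posthoc} data frame
#'   (pair, diff, p_adj).
#' @export
group_compare <- function(groups, design = c("TWO_GROUP", "MULTI_GROUP"),
                          var_equal = TRUE) {
  design <- match.arg(design)
  if (any(vapply(groups, length, 0L) < 2)) {
    stop("every group needs at least 2 values")
  }
  if (design == "TWO_GROUP") {
    if (length(groups) != 2) stop("TWO_GROUP design needs exactly 2 groups")
    x <- groups[[1]]; y <- groups[[2]]
    tt <- tryCatch(
      stats::t.test(x, y, var.equal = var_equal, alternative = "two.sided"),
      error = function(e) {
        # zero-variance groups: t.test refuses; the statistic is still defined
        d <- mean(x) - mean(y)
        list(statistic = if (d == 0) 0 else sign(d) * Inf,
             parameter = length(x) + length(y) - 2,
             p.value = if (d == 0) 1 else 0)
      })
    return(list(method = "two-tailed two-sample t-test",
                statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value))
  }
  if (length(groups) < 3) stop("MULTI_GROUP design needs >= 3 groups")
  dat <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 0L)))
  )
  fit <- stats::aov(value ~ group, data = dat)
  an <- summary(fit)[[1]]
  fstat <- an[["F value"]][1]
  pval <- an[["Pr(>F)"]][1]
  if (is.nan(fstat)) { fstat <- 0; pval <- 1 }  # 0/0: no variance anywhere
  tk <- stats::TukeyHSD(fit)$group
  posthoc <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                        p_adj = tk[, "p adj"], row.names = NULL,
                        stringsAsFactors = FALSE)
  list(method = "one-way ANOVA + Tukey HSD",
       statistic = unname(fstat), df = unname(an[["Df"]]),
       p_value = unname(pval), posthoc = posthoc)
}
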