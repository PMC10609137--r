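# Lipid-panel group statistics: subtype Kruskal-Wallis, Control-vs-IBS
# Mann-Whitney, fold changes and Z-score profiles.

align_panel_metadata <- function(panel, metadata) {
  common <- intersect(rownames(panel), metadata$sample_id)
  if (!length(common)) stop("no shared samples between panel and metadata")
  list(panel = panel[common, , drop = FALSE],
       metadata = metadata[match(common, metadata$sample_id), , drop = FALSE])
}

#' Log2 fold change of lipid concentrations, IBS vs Control
#'
#' log2(center_IBS / center_Control) per lipid; positive means higher in
#' IBS. Group centers are means by default (medians optional).
#'
#' @param panel samples x lipids concentration matrix (LLOQ-substituted).
#' @param metadata metadata with `ibs_status`.
#' @param center "mean" or "median".
#' @return named numeric vector per lipid.
#' @export
log_fold_change <- function(panel, metadata, center = c("mean", "median")) {
  center <- match.arg(center)
  al <- align_panel_metadata(panel, metadata)
  fun <- if (center == "mean") colMeans else
    function(m) apply(m, 2, median)
  ibs <- al$metadata$ibs_status == "IBS"
  a <- fun(al$panel[ibs, , drop = FALSE])
  b <- fun(al$panel[!ibs, , drop = FALSE])
  if (any(a <= 0) || any(b <= 0)) stop("non-positive group center")
  log2(a / b)
}

#' Per-lipid group tests
#'
#' Kruskal-Wallis across the four groups, two-sided Mann-Whitney U for
#' Control vs pooled IBS (U oriented as the number of (Control, IBS) pairs
#' with the Control value larger), log2 fold change (IBS vs Control), and
#' uncorrected p < 0.05 significance flags.
#'
#' @param panel samples x lipids concentration matrix.
#' @param metadata metadata with `group` and `ibs_status`.
#' @param alpha flag level (default 0.05, uncorrected).
#' @return data.frame: lipid, class, H, p_kw, U, p_mw, log2fc, sig_kw,
#'   sig_mw.
#' @export
lipid_group_tests <- function(panel, metadata, alpha = 0.05) {
  al <- align_panel_metadata(panel, metadata)
  panel <- al$panel; metadata <- al$metadata
  groups_obs <- droplevels(metadata$group)
  if (nlevels(groups_obs) < 2 || !any(metadata$ibs_status == "Control") ||
      !any(metadata$ibs_status == "IBS"))
    stop("empty group: need Control plus at least one IBS group")
  cls <- attr(panel, "lipid_class")
  if (is.null(cls)) cls <- lipid_unsaturation_class(colnames(panel))
  ctrl <- metadata$ibs_status == "Control"
  lfc <- log_fold_change(panel, metadata)
  rows <- lapply(colnames(panel), function(lp) {
    x <- panel[, lp]
    kt <- kruskal_wallis(x, groups_obs)
    wt <- suppressWarnings(wilcox.test(x[ctrl], x[!ctrl]))
    data.frame(lipid = lp, class = unname(cls[lp]), H = kt$H, p_kw = kt$p,
               U = unname(wt$statistic), p_mw = wt$p.value,
               log2fc = unname(lfc[lp]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$sig_kw <- out$p_kw < alpha
  out$sig_mw <- out$p_mw < alpha
  out
}

#' Per-group mean Z-score profile of the lipid panel
#'
#' Each lipid is Z-scored over all samples jointly, then averaged within
#' group (the radar-plot statistic). Constant lipids are excluded with a
#' warning.
#'
#' @param panel samples x lipids concentration matrix.
#' @param metadata metadata with `group`.
#' @return groups x lipids matrix of mean Z-scores.
#' @export
z_profile <- function(panel, metadata) {
  al <- align_panel_metadata(panel, metadata)
  panel <- al$panel; metadata <- al$metadata
  sds <- apply(panel, 2, sd)
  if (any(sds == 0)) {
    warning("excluding constant lipid(s): ",
            paste(colnames(panel)[sds == 0], collapse = ", "))
    panel <- panel[, sds > 0, drop = FALSE]
  }
  Z <- scale(panel)
  g <- droplevels(metadata$group)
  out <- rowsum(Z, g) / as.vector(table(g))
  out[intersect(GROUP_LEVELS, rownames(out)), , drop = FALSE]
}
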