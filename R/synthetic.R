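# Synthetic paired microbiome/lipidome/metadata generator.
#
# The generator emulates a four-group IBS case-control design: compositional
# ASV counts on a random rooted binary phylogeny, with (i) planted modules of
# co-occurring taxa driven by per-sample latent factors, (ii) a planted
# phylogenetic balance whose log-ratio tracks monthly HFCS consumption,
# (iii) group shifts in named fecal fatty acids, and (iv) latent-factor
# coupling between the microbiome and the lipid panel. Every planted piece
# is returned as machine-readable truth so downstream stages can be scored
# on recovery.

#' The 30-lipid fecal fatty-acid panel
#' @return character vector of 30 shorthand fatty-acid names.
#' @export
default_lipid_names <- function() {
  c("8:0", "10:0", "12:0", "14:0", "15:0", "16:0", "17:0", "18:0",
    "20:0", "22:0", "24:0",
    "18:1n9", "20:1n9", "22:1n9", "24:1n9",
    "18:2n6", "18:3n6", "20:2n6", "20:3n6", "20:4n6", "22:4n6",
    "18:3n3", "20:3n3", "20:5n3", "22:5n3", "22:6n3",
    "14:1n5", "16:1n7", "18:1n7", "22:1n11")
}

#' Generator design for the synthetic study
#'
#' Defaults mirror the emulated study: 45 samples in four groups
#' (12 Control, 10 IBS-D, 13 IBS-M, 10 IBS-C), 255 taxa on a binary rooted
#' tree, ~60,000 reads per sample, three planted 12-taxon co-occurrence
#' modules (latent-factor loading 2), one planted HFCS-associated balance
#' (slope 1 on the log-ratio per SD of HFCS), IBS-shifted fatty acids, and
#' latent-factor coupling of strength 1 linking taxa and lipids. HFCS is
#' log-normal in grams/month with a higher mean in IBS groups.
#'
#' @param n_per_group named integer vector over
#'   Control/IBS-D/IBS-M/IBS-C.
#' @param n_taxa number of taxa (tree leaves).
#' @param depth expected reads per sample before rarefaction.
#' @param n_modules,module_size,module_loading planted module structure.
#' @param hfcs_slope slope of the planted balance on the log-ratio scale per
#'   standard deviation of HFCS consumption.
#' @param group_effect_scale multiplier on the default per-taxon group
#'   shifts (0 disables them).
#' @param lipid_effect_scale multiplier on the default per-lipid group
#'   shifts (0 disables them).
#' @param coupling_strength loading of the shared latent factors in lipid
#'   log-concentrations (0 decouples the two datasets).
#' @param noise_sd iid log-abundance noise.
#' @param lipid_noise_sd iid lipid log-concentration noise.
#' @param hfcs_meanlog_control,hfcs_meanlog_ibs,hfcs_sdlog log-normal HFCS
#'   parameters (g/month).
#' @return a `mblink_design` list.
#' @export
generator_design <- function(n_per_group = c("Control" = 12, "IBS-D" = 10,
                                             "IBS-M" = 13, "IBS-C" = 10),
                             n_taxa = 255, depth = 60000,
                             n_modules = 3, module_size = 12,
                             module_loading = 2,
                             hfcs_slope = 1,
                             group_effect_scale = 1,
                             lipid_effect_scale = 1,
                             coupling_strength = 1,
                             noise_sd = 0.5,
                             lipid_noise_sd = 0.5,
                             hfcs_meanlog_control = log(3000),
                             hfcs_meanlog_ibs = log(8000),
                             hfcs_sdlog = 0.6) {
  stopifnot(identical(names(n_per_group), GROUP_LEVELS),
            all(n_per_group >= 1), n_taxa >= 2,
            n_modules * module_size < n_taxa)
  structure(list(
    n_per_group = n_per_group, n_taxa = n_taxa, depth = depth,
    n_modules = n_modules, module_size = module_size,
    module_loading = module_loading, hfcs_slope = hfcs_slope,
    group_effect_scale = group_effect_scale,
    lipid_effect_scale = lipid_effect_scale,
    coupling_strength = coupling_strength,
    noise_sd = noise_sd, lipid_noise_sd = lipid_noise_sd,
    hfcs_meanlog_control = hfcs_meanlog_control,
    hfcs_meanlog_ibs = hfcs_meanlog_ibs, hfcs_sdlog = hfcs_sdlog,
    lipid_names = default_lipid_names()
  ), class = "mblink_design")
}

#' Null-generator design (no planted group or diet effects)
#'
#' Zeroes every group-linked effect (group shifts, HFCS-balance slope,
#' lipid shifts, microbiome-lipidome coupling) while keeping the latent
#' co-occurrence structure, so that group labels are exchangeable and every
#' downstream test is calibrated. Defaults to the lighter calibration size
#' (45 samples, 100 taxa, depth 5,000).
#'
#' @param n_taxa,depth see [generator_design()].
#' @param ... further overrides passed to [generator_design()].
#' @return a `mblink_design` list.
#' @export
null_design <- function(n_taxa = 100, depth = 5000, ...) {
  generator_design(n_taxa = n_taxa, depth = depth,
                   hfcs_slope = 0, group_effect_scale = 0,
                   lipid_effect_scale = 0, coupling_strength = 0,
                   hfcs_meanlog_ibs = log(3000), ...)
}

#' Generate a random rooted binary phylogeny
#'
#' Sequential random joins of lineages with exponential(1) branch lengths;
#' leaves are named "ASV0001", "ASV0002", ...
#'
#' @param n_taxa number of leaves (>= 2).
#' @param seed integer seed.
#' @return a rooted binary `phylo` tree.
#' @export
generate_tree <- function(n_taxa, seed = NULL) {
  stopifnot(n_taxa >= 2)
  local_seed(seed, {
    tree <- ape::rtree(n_taxa, rooted = TRUE,
                       br = function(n) round(rexp(n), 6))
  })
  tree$tip.label <- sprintf("ASV%04d", seq_len(n_taxa))
  tree
}

# Choose the planted structure on a given tree: the HFCS balance node
# (an internal node whose two child subtrees both hold 4-16 leaves,
# preferring the most size-balanced such node) and disjoint module taxon
# sets sampled from the remaining taxa.
plant_structure <- function(tree, design, seed = NULL) {
  basis <- build_balance_basis(tree)
  sizes_num <- lengths(basis$numerator)
  sizes_den <- lengths(basis$denominator)
  needed <- design$n_modules * design$module_size
  ok <- sizes_num >= 4 & sizes_num <= 16 & sizes_den >= 4 & sizes_den <= 16 &
    design$n_taxa - (sizes_num + sizes_den) >= needed
  if (!any(ok)) stop("no internal node with 4-16 leaves on both sides ",
                     "leaving room for the planted modules")
  pick <- which(ok)[which.max(pmin(sizes_num[ok], sizes_den[ok]))]
  balance <- list(label = basis$label[pick],
                  numerator = basis$numerator[[pick]],
                  denominator = basis$denominator[[pick]],
                  slope = design$hfcs_slope)
  balance_taxa <- c(balance$numerator, balance$denominator)
  pool <- setdiff(tree$tip.label, balance_taxa)
  local_seed(seed, {
    chosen <- sample(pool, needed)
  })
  modules <- split(chosen, rep(seq_len(design$n_modules),
                               each = design$module_size))
  names(modules) <- paste0("M", seq_len(design$n_modules))
  list(balance = balance, modules = modules)
}

# Default per-taxon group shifts (log scale), scaled by group_effect_scale:
# module 1 taxa depleted in every IBS group; module 3 taxa enriched in
# IBS-C; one non-module taxon strongly depleted in IBS and another enriched
# in IBS-C/IBS-M (mirroring single-taxon differential-abundance findings).
group_effect_matrix <- function(design, taxa, planted) {
  G <- matrix(0, 4, length(taxa), dimnames = list(GROUP_LEVELS, taxa))
  s <- design$group_effect_scale
  if (s == 0) return(G)
  ibs <- GROUP_LEVELS != "Control"
  G[ibs, planted$modules[[1]]] <- -0.8 * s
  if (design$n_modules >= 3) G["IBS-C", planted$modules[[3]]] <- 0.8 * s
  free <- setdiff(taxa, c(unlist(planted$modules),
                          planted$balance$numerator,
                          planted$balance$denominator))
  if (length(free) >= 2) {
    G[ibs, free[1]] <- -1.5 * s
    G[c("IBS-M", "IBS-C"), free[2]] <- 2.0 * s
  }
  G
}

# Default per-lipid group shifts (log scale): palmitic (16:0) up in IBS-C,
# margaric (17:0) up in IBS-M/IBS-C, gamma-linolenic (18:3n6) strongly down
# in all IBS (>2-fold higher in Control), linoleic (18:2n6) and
# alpha-linolenic (18:3n3) down in IBS.
lipid_effect_matrix <- function(design) {
  L <- matrix(0, 4, length(design$lipid_names),
              dimnames = list(GROUP_LEVELS, design$lipid_names))
  s <- design$lipid_effect_scale
  if (s == 0) return(L)
  ibs <- GROUP_LEVELS != "Control"
  L["IBS-C", "16:0"] <- 0.6 * s
  L[c("IBS-M", "IBS-C"), "17:0"] <- 0.5 * s
  L[ibs, "18:3n6"] <- -0.9 * s
  L[ibs, "18:2n6"] <- -0.4 * s
  L[ibs, "18:3n3"] <- -0.4 * s
  L
}

#' Generate sample metadata
#'
#' Group labels per design; HFCS consumption (g/month) log-normal with a
#' higher mean in IBS groups; socioeconomic covariates (income bracket,
#' marital status, weekly alcohol consumption, household occupants) drawn
#' from fixed categorical distributions.
#'
#' @param design a `mblink_design`.
#' @param seed integer seed.
#' @return validated metadata data.frame (45 samples by default).
#' @export
generate_metadata <- function(design, seed = NULL) {
  n <- sum(design$n_per_group)
  group <- rep(GROUP_LEVELS, times = design$n_per_group)
  local_seed(seed, {
    meanlog <- ifelse(group == "Control", design$hfcs_meanlog_control,
                      design$hfcs_meanlog_ibs)
    hfcs <- rlnorm(n, meanlog = meanlog, sdlog = design$hfcs_sdlog)
    income <- sample(c("<25k", "25-50k", "50-100k"), n, replace = TRUE,
                     prob = c(0.5, 0.3, 0.2))
    marital <- sample(c("Single", "Married", "Separated/Divorced", "Widowed"),
                      n, replace = TRUE, prob = c(0.5, 0.35, 0.08, 0.07))
    alcohol <- round(rexp(n, rate = 1 / 3), 1)
    occupants <- sample(1:6, n, replace = TRUE,
                        prob = c(0.25, 0.3, 0.2, 0.12, 0.08, 0.05))
  })
  df <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    group = group,
    hfcs_monthly = round(hfcs, 1),
    income_bracket = factor(income, levels = c("<25k", "25-50k", "50-100k"),
                            ordered = TRUE),
    marital_status = marital,
    alcohol = alcohol,
    occupants = occupants,
    stringsAsFactors = FALSE)
  validate_sample_metadata(df)
}

#' Generate compositional ASV counts with planted structure
#'
#' Per sample, taxon log-abundances are the sum of a taxon baseline, the
#' group effect, latent-factor module loadings, an antisymmetric
#' HFCS-balance term (+slope/2 on numerator taxa, -slope/2 on denominator
#' taxa, per SD of HFCS), and iid Gaussian noise; a softmax maps them to a
#' composition from which a multinomial read count is drawn.
#'
#' @param tree phylogeny from [generate_tree()].
#' @param design a `mblink_design`.
#' @param metadata metadata from [generate_metadata()]; generated internally
#'   (same seed stream) when NULL.
#' @param seed integer seed.
#' @return list with `counts` (samples x taxa integer matrix), `factors`
#'   (samples x modules latent factors), `metadata`, and `truth` (planted
#'   modules, balance, effect matrices).
#' @export
generate_counts <- function(tree, design, metadata = NULL, seed = NULL) {
  taxa <- tree$tip.label
  if (length(taxa) != design$n_taxa)
    stop("tree has ", length(taxa), " leaves but design expects ",
         design$n_taxa)
  seeds <- derive_seeds(seed, 4L)
  if (is.null(metadata)) metadata <- generate_metadata(design, seeds[1])
  planted <- plant_structure(tree, design, seeds[2])
  n <- nrow(metadata)
  m <- length(taxa)
  G <- group_effect_matrix(design, taxa, planted)
  bal_sign <- setNames(rep(0, m), taxa)
  bal_sign[planted$balance$numerator] <- 0.5
  bal_sign[planted$balance$denominator] <- -0.5
  z <- as.numeric(scale(metadata$hfcs_monthly))
  planted_taxa <- c(unlist(planted$modules), planted$balance$numerator,
                    planted$balance$denominator)
  local_seed(seeds[3], {
    # wide baseline spread mimics steep rank-abundance curves, so taxa are
    # conditionally absent and presence/absence metrics carry signal
    baseline <- rnorm(m, 0, 2)
    names(baseline) <- taxa
    # planted taxa kept moderately abundant so their signal survives
    # multinomial sampling
    baseline[planted_taxa] <- rnorm(length(planted_taxa), 0.5, 0.5)
    Fmat <- matrix(rnorm(n * design$n_modules), n, design$n_modules,
                   dimnames = list(metadata$sample_id,
                                   names(planted$modules)))
    noise <- matrix(rnorm(n * m, 0, design$noise_sd), n, m)
    depth_i <- pmax(1L, round(design$depth * runif(n, 0.95, 1.15)))
    eta <- matrix(baseline, n, m, byrow = TRUE) +
      G[as.character(metadata$group), , drop = FALSE] +
      outer(z, bal_sign) * design$hfcs_slope + noise
    for (k in seq_len(design$n_modules)) {
      idx <- match(planted$modules[[k]], taxa)
      eta[, idx] <- eta[, idx] + design$module_loading * Fmat[, k]
    }
    prob <- exp(eta - apply(eta, 1, max))
    prob <- prob / rowSums(prob)
    counts <- t(vapply(seq_len(n),
                       function(i) rmultinom(1, depth_i[i], prob[i, ])[, 1],
                       integer(m)))
  })
  dimnames(counts) <- list(metadata$sample_id, taxa)
  storage.mode(counts) <- "integer"
  truth <- list(modules = planted$modules, balance = planted$balance,
                group_effects = G, module_loading = design$module_loading)
  list(counts = counts, factors = Fmat, metadata = metadata, truth = truth)
}

#' Generate the fecal lipid panel
#'
#' Log-normal concentrations (ug/g dry mass) with per-group shifts in named
#' fatty acids; the shared latent factors from [generate_counts()] load
#' into disjoint 5-lipid blocks with weight `coupling_strength`, creating
#' microbiome-lipidome concordance. Values below 0.001 are clamped to the
#' LLOQ substitution value.
#'
#' @param design a `mblink_design`.
#' @param metadata metadata data.frame.
#' @param factors samples x modules latent-factor matrix (required when
#'   `coupling_strength > 0`).
#' @param seed integer seed.
#' @return samples x lipids concentration matrix with `unit`/`class`
#'   attributes, plus a `coupled_lipids` attribute naming the truth.
#' @export
generate_lipids <- function(design, metadata, factors = NULL, seed = NULL) {
  lipids <- design$lipid_names
  n <- nrow(metadata)
  p <- length(lipids)
  if (design$coupling_strength > 0 && is.null(factors))
    stop("latent factors required when coupling_strength > 0")
  L <- lipid_effect_matrix(design)
  cls <- lipid_unsaturation_class(lipids)
  coupled <- list()
  local_seed(seed, {
    base <- ifelse(cls == "saturated", log(800), log(60)) + rnorm(p, 0, 0.8)
    logc <- matrix(base, n, p, byrow = TRUE) +
      L[as.character(metadata$group), , drop = FALSE] +
      matrix(rnorm(n * p, 0, design$lipid_noise_sd), n, p)
  })
  if (design$coupling_strength > 0) {
    for (k in seq_len(ncol(factors))) {
      idx <- ((k - 1) * 5 + 1):(k * 5)
      idx <- idx[idx <= p]
      logc[, idx] <- logc[, idx] + design$coupling_strength * factors[, k]
      coupled[[colnames(factors)[k]]] <- lipids[idx]
    }
  }
  conc <- exp(logc)
  conc[conc < 0.001] <- 0.001
  dimnames(conc) <- list(metadata$sample_id, lipids)
  attr(conc, "unit") <- "ug/g dry mass"
  attr(conc, "lipid_class") <- cls
  attr(conc, "coupled_lipids") <- coupled
  conc
}

#' Simulate a complete paired study
#'
#' Generates tree, metadata, counts and lipid panel from one root seed
#' (split deterministically per stage) and optionally writes the four input
#' files plus a JSON truth file for recovery scoring.
#'
#' @param design a `mblink_design`.
#' @param seed root integer seed.
#' @param dir optional output directory; created if missing.
#' @return list with `tree`, `metadata`, `counts`, `lipids`, `factors`,
#'   `truth`, and (if written) `paths`.
#' @export
simulate_study <- function(design = generator_design(), seed = 1,
                           dir = NULL) {
  seeds <- derive_seeds(seed, 4L)
  tree <- generate_tree(design$n_taxa, seeds[1])
  metadata <- generate_metadata(design, seeds[2])
  gc <- generate_counts(tree, design, metadata, seeds[3])
  lipids <- generate_lipids(design, metadata, gc$factors, seeds[4])
  truth <- gc$truth
  truth$coupled_lipids <- attr(lipids, "coupled_lipids")
  truth$coupling_strength <- design$coupling_strength
  truth$seed <- seed
  out <- list(tree = tree, metadata = metadata, counts = gc$counts,
              lipids = lipids, factors = gc$factors, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      counts = file.path(dir, "feature_table.tsv"),
      tree = file.path(dir, "tree.nwk"),
      metadata = file.path(dir, "metadata.tsv"),
      lipids = file.path(dir, "lipids.csv"),
      truth = file.path(dir, "truth.json"))
    write_feature_table(gc$counts, paths$counts)
    write_newick(tree, paths$tree)
    write_sample_metadata(metadata, paths$metadata)
    write_lipid_panel(lipids, paths$lipids)
    truth_json <- truth
    truth_json$group_effects <- NULL  # dense matrix; modules/balance suffice
    jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                         digits = NA)
    out$paths <- paths
  }
  out
}
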