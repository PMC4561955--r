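CORE_CATEGORIES <- c("CONSERVED", "ADDITIVITY", "ELD_P1", "ELD_P2",
                     "TRANSGRESSIVE_UP", "TRANSGRESSIVE_DOWN")
SPECIFIC_CATEGORIES <- c("SPECIFIC_P1", "SPECIFIC_P2", "SPECIFIC_F1",
                         "SPECIFIC_F2")

#' Simulation parameters for the hybrid-trio generator
#'
#' The generator emulates the data regime of an unreplicated hybrid-parent
#' quartet: one pooled library per sample, log-normal baseline abundances
#' (in counts-per-million units), negative-binomial counts, and planted
#' expression categories whose proportions default to the rough shape seen
#' in hybrid-fish transcriptomes (about a third of genes undifferentiated
#' between the parents, ELD genes a quarter, additivity a minority).
#'
#' @param n_genes,n_mirnas feature counts (defaults 2000 and 300).
#' @param category_proportions named proportions over the six core
#'   categories plus the four SPECIFIC_* sample-exclusive ones; must sum
#'   to 1.
#' @param fold_effect planted fold difference delta between diverged means
#'   (default 8; must be >= 1).
#' @param baseline_logmean,baseline_logsd log-normal parameters of the
#'   per-gene baseline abundance in CPM units (defaults log(30) and 1).
#' @param nb_dispersion NB dispersion phi with variance mu + phi mu^2;
#'   0 means Poisson (default 0.05).
#' @param library_sizes four mapped-fragment totals named P1, P2, F1, F2
#'   (default 1e7 each).
#' @param f2_inherit_prob probability that a gene's F2 category repeats its
#'   F1 category (default 0.9).
#' @param mirna_coupling_beta slope of the planted miRNA-target repression,
#'   target log2FC = -beta * miRNA log2FC + noise (default 1).
#' @param mirna_noise_sd sd of that coupling noise in log2 units
#'   (default 0.25).
#' @param mirna_coupled_frac fraction of miRNAs carrying coupled targets
#'   (default 0.3).
#' @param targets_per_mirna integer range of targets per coupled miRNA
#'   (default 2 to 8).
#' @param gene_length_range transcript length interval in bp (default
#'   500 to 5000).
#' @param seed root seed; every stream derives from it.
#' @return validated list of class \code{sim_params}.
#' @export
sim_params <- function(n_genes = 2000, n_mirnas = 300,
                       category_proportions = c(
                         CONSERVED = 0.30, ADDITIVITY = 0.10,
                         ELD_P1 = 0.125, ELD_P2 = 0.125,
                         TRANSGRESSIVE_UP = 0.10, TRANSGRESSIVE_DOWN = 0.10,
                         SPECIFIC_P1 = 0.0375, SPECIFIC_P2 = 0.0375,
                         SPECIFIC_F1 = 0.0375, SPECIFIC_F2 = 0.0375),
                       fold_effect = 8, baseline_logmean = log(30),
                       baseline_logsd = 1, nb_dispersion = 0.05,
                       library_sizes = c(P1 = 1e7, P2 = 1e7,
                                         F1 = 1e7, F2 = 1e7),
                       f2_inherit_prob = 0.9, mirna_coupling_beta = 1,
                       mirna_noise_sd = 0.25, mirna_coupled_frac = 0.3,
                       targets_per_mirna = c(2L, 8L),
                       gene_length_range = c(500L, 5000L), seed = 1L) {
  all_cats <- c(CORE_CATEGORIES, SPECIFIC_CATEGORIES)
  if (!all(names(category_proportions) %in% all_cats)) {
    stop("unknown category in proportions", call. = FALSE)
  }
  pr <- stats::setNames(rep(0, length(all_cats)), all_cats)
  pr[names(category_proportions)] <- category_proportions
  if (abs(sum(pr) - 1) > 1e-9 || any(pr < 0)) {
    stop("category proportions must be non-negative and sum to 1",
         call. = FALSE)
  }
  stopifnot(n_genes >= 1, n_mirnas >= 0, fold_effect >= 1,
            baseline_logsd >= 0, nb_dispersion >= 0,
            length(library_sizes) == 4, all(library_sizes > 0),
            f2_inherit_prob >= 0, f2_inherit_prob <= 1,
            mirna_noise_sd >= 0, mirna_coupled_frac >= 0,
            mirna_coupled_frac <= 1, length(targets_per_mirna) == 2,
            targets_per_mirna[1] >= 1,
            targets_per_mirna[2] >= targets_per_mirna[1],
            length(gene_length_range) == 2, gene_length_range[1] >= 1,
            gene_length_range[2] >= gene_length_range[1])
  if (is.null(names(library_sizes))) names(library_sizes) <- SAMPLE_LABELS
  structure(list(n_genes = as.integer(n_genes),
                 n_mirnas = as.integer(n_mirnas),
                 category_proportions = pr, fold_effect = fold_effect,
                 baseline_logmean = baseline_logmean,
                 baseline_logsd = baseline_logsd,
                 nb_dispersion = nb_dispersion,
                 library_sizes = library_sizes[SAMPLE_LABELS],
                 f2_inherit_prob = f2_inherit_prob,
                 mirna_coupling_beta = mirna_coupling_beta,
                 mirna_noise_sd = mirna_noise_sd,
                 mirna_coupled_frac = mirna_coupled_frac,
                 targets_per_mirna = as.integer(targets_per_mirna),
                 gene_length_range = as.integer(gene_length_range),
                 seed = as.integer(seed)),
            class = "sim_params")
}

# Parent means for one feature: low parent at lambda, high at delta*lambda.
# polarity 1 means P1 is the high parent. Transgressive features keep equal
# parents when parents_equal is TRUE.
parent_means <- function(category, lambda, delta, polarity, parents_equal) {
  if (category == "CONSERVED") return(c(lambda, lambda))
  if (category == "SPECIFIC_P1") return(c(lambda, 0))
  if (category == "SPECIFIC_P2") return(c(0, lambda))
  if (category %in% c("SPECIFIC_F1", "SPECIFIC_F2")) return(c(0, 0))
  if (category %in% c("TRANSGRESSIVE_UP", "TRANSGRESSIVE_DOWN") &&
      parents_equal) {
    return(c(lambda, lambda))
  }
  if (polarity == 1) c(delta * lambda, lambda) else c(lambda, delta * lambda)
}

hybrid_mean <- function(category, mu1, mu2, lambda, delta, generation) {
  switch(category,
         CONSERVED = lambda,
         ADDITIVITY = (mu1 + mu2) / 2,
         ELD_P1 = mu1,
         ELD_P2 = mu2,
         TRANSGRESSIVE_UP = delta * max(mu1, mu2),
         TRANSGRESSIVE_DOWN = min(mu1, mu2) / delta,
         SPECIFIC_P1 = 0,
         SPECIFIC_P2 = 0,
         SPECIFIC_F1 = if (generation == "F1") lambda else 0,
         SPECIFIC_F2 = if (generation == "F2") lambda else 0,
         stop("unknown category: ", category, call. = FALSE))
}

draw_counts <- function(mu, depth, phi) {
  m <- mu * depth / 1e6
  if (phi == 0) stats::rpois(length(m), m)
  else stats::rnbinom(length(m), size = 1 / phi, mu = m)
}

# Noise-free relation between two true means as the fold-gated caller
# would see them at infinite precision: equal means are NS; unequal means
# are significant, so only the strict fold gate (on count-scale values
# with the pseudocount) decides.
expected_relation <- function(mu_a, mu_b, depth_a, depth_b, fc,
                              pseudocount = 1) {
  ca <- mu_a * depth_a / 1e6 + pseudocount
  cb <- mu_b * depth_b / 1e6 + pseudocount
  ifelse(mu_a == mu_b, "NS",
         ifelse(ca / cb > fc, "GT", ifelse(cb / ca > fc, "LT", "NS")))
}

expected_group_for <- function(mu, depths, generation, fc) {
  h <- generation
  rel_pp <- expected_relation(mu[, "P1"], mu[, "P2"],
                              depths[["P1"]], depths[["P2"]], fc)
  rel_h1 <- expected_relation(mu[, h], mu[, "P1"],
                              depths[[h]], depths[["P1"]], fc)
  rel_h2 <- expected_relation(mu[, h], mu[, "P2"],
                              depths[[h]], depths[["P2"]], fc)
  classify_trio(rel_pp, rel_h1, rel_h2)
}

#' Simulate a hybrid-trio count table with planted truth
#'
#' Draws per-gene log-normal baselines, assigns planted categories at the
#' configured proportions, builds true per-sample means from the category
#' recipes (parents diverged by \code{fold_effect} with random polarity,
#' hybrids at the parent value, mid-parent value, or beyond both parents),
#' lets each gene's F2 category repeat its F1 category with probability
#' \code{f2_inherit_prob} (otherwise re-drawn among categories compatible
#' with the fixed parental means; sample-exclusive genes always inherit),
#' and draws NB counts at the configured library depths.
#'
#' The truth table records both the planted recipe and the *expected*
#' classification — the bin/group the fold-gated caller would output on
#' the true means with no sampling noise. Recovery tests compare observed
#' calls against the expected group, since some recipes (an exactly
#' mid-parent hybrid, in particular) legitimately sit on the other side of
#' the fold gate from their recipe's name.
#'
#' @param params a \code{\link{sim_params}}.
#' @param fc fold gate used for the expected classification (default 2,
#'   matching the analysis default).
#' @return list: \code{counts} (a \code{\link{count_table}} whose library
#'   sizes are the nominal depths), \code{meta} (gene metadata with
#'   simulated lengths and term annotations), \code{truth} (data frame:
#'   gene_id, planted category and expected bin/group per generation, true
#'   means per sample).
#' @export
simulate_trio <- function(params = sim_params(), fc = 2) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_genes
  delta <- params$fold_effect
  gene_ids <- sprintf("g%04d", seq_len(n))
  lambda <- stats::rlnorm(n, params$baseline_logmean, params$baseline_logsd)
  cats <- names(params$category_proportions)
  cat_f1 <- sample(cats, n, replace = TRUE,
                   prob = params$category_proportions)
  polarity <- sample(1:2, n, replace = TRUE)
  parents_equal <- stats::runif(n) < 0.5
  pm <- t(mapply(parent_means, cat_f1, lambda,
                 MoreArgs = list(delta = delta),
                 polarity = polarity, parents_equal = parents_equal))
  inherit <- stats::runif(n) < params$f2_inherit_prob
  cat_f2 <- cat_f1
  base_pr <- params$category_proportions
  for (i in which(!inherit)) {
    if (cat_f1[i] %in% SPECIFIC_CATEGORIES) next
    compatible <- if (pm[i, 1] == pm[i, 2]) {
      c("CONSERVED", "TRANSGRESSIVE_UP", "TRANSGRESSIVE_DOWN")
    } else {
      c("ADDITIVITY", "ELD_P1", "ELD_P2", "TRANSGRESSIVE_UP",
        "TRANSGRESSIVE_DOWN")
    }
    w <- base_pr[compatible]
    cat_f2[i] <- sample(compatible, 1, prob = w / sum(w))
  }
  mu <- cbind(
    P1 = pm[, 1], P2 = pm[, 2],
    F1 = mapply(hybrid_mean, cat_f1, pm[, 1], pm[, 2], lambda,
                MoreArgs = list(delta = delta, generation = "F1")),
    F2 = mapply(hybrid_mean, cat_f2, pm[, 1], pm[, 2], lambda,
                MoreArgs = list(delta = delta, generation = "F2")))
  depths <- params$library_sizes
  counts <- vapply(SAMPLE_LABELS,
                   function(s) draw_counts(mu[, s], depths[[s]],
                                           params$nb_dispersion),
                   numeric(n))
  ct <- count_table(counts, gene_ids, SAMPLE_LABELS,
                    library_sizes = pmax(depths, colSums(counts)))
  exp_f1 <- expected_group_for(mu, depths, "F1", fc)
  exp_f2 <- expected_group_for(mu, depths, "F2", fc)
  lengths <- sample(seq(params$gene_length_range[1],
                        params$gene_length_range[2]), n, replace = TRUE)
  vocab <- sprintf("GO:SIM%04d", 1:40)
  go <- lapply(seq_len(n), function(i) {
    k <- stats::rpois(1, 2)
    terms <- if (k > 0) sample(vocab, min(k, 40)) else character(0)
    # one term planted as enriched among ELD genes so term enrichment has
    # signal to find
    if (cat_f1[i] %in% c("ELD_P1", "ELD_P2") && stats::runif(1) < 0.5) {
      terms <- union(terms, "GO:SIM0001")
    }
    terms
  })
  meta <- data.frame(gene_id = gene_ids, length_bp = as.integer(lengths),
                     stringsAsFactors = FALSE)
  meta$go_terms <- go
  rownames(meta) <- gene_ids
  truth <- data.frame(gene_id = gene_ids, category_f1 = cat_f1,
                      category_f2 = cat_f2,
                      expected_bin_f1 = exp_f1$bin,
                      expected_group_f1 = exp_f1$group,
                      expected_bin_f2 = exp_f2$bin,
                      expected_group_f2 = exp_f2$group,
                      mu_P1 = mu[, "P1"], mu_P2 = mu[, "P2"],
                      mu_F1 = mu[, "F1"], mu_F2 = mu[, "F2"],
                      stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(counts = ct, meta = meta, truth = truth, params = params)
}

#' Simulate a coupled miRNA layer over a gene simulation
#'
#' Simulates miRNA counts with the same category machinery, then plants
#' miRNA-mediated repression: a configurable fraction of miRNAs with
#' nonzero true log2 fold change versus the mid-parent value (m) get
#' targets among the simulated genes, and each target's hybrid mean is
#' re-set so that its log2FC-vs-MPV equals \code{-beta * m} plus Gaussian
#' noise, per generation. Target counts in the hybrid columns are re-drawn
#' from the adjusted means. The map gains extra unadjusted links from
#' uncoupled miRNAs so it is many-to-many in both directions.
#'
#' @param params the \code{\link{sim_params}} used for the gene layer.
#' @param gene_sim result of \code{\link{simulate_trio}}.
#' @return list: \code{mirna_counts} (count_table), \code{target_map}
#'   (mirna_id, gene_id), \code{mirna_truth} (planted category, true m per
#'   generation, coupled flag), \code{gene_counts} (count_table with
#'   adjusted hybrid columns), \code{gene_truth} (gene truth with
#'   \code{target_of} and true coupled fold changes).
#' @export
simulate_mirna_layer <- function(params, gene_sim) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + 1000003L)
  n <- params$n_mirnas
  if (n < 1) stop("n_mirnas must be >= 1 for the miRNA layer", call. = FALSE)
  delta <- params$fold_effect
  ids <- sprintf("mir%03d", seq_len(n))
  lambda <- stats::rlnorm(n, params$baseline_logmean, params$baseline_logsd)
  cats <- names(params$category_proportions)
  # sample-exclusive miRNAs are not part of the emulated regime
  pr <- params$category_proportions[CORE_CATEGORIES]
  cat_f1 <- sample(CORE_CATEGORIES, n, replace = TRUE, prob = pr / sum(pr))
  polarity <- sample(1:2, n, replace = TRUE)
  parents_equal <- stats::runif(n) < 0.5
  pm <- t(mapply(parent_means, cat_f1, lambda,
                 MoreArgs = list(delta = delta),
                 polarity = polarity, parents_equal = parents_equal))
  inherit <- stats::runif(n) < params$f2_inherit_prob
  cat_f2 <- cat_f1
  for (i in which(!inherit)) {
    compatible <- if (pm[i, 1] == pm[i, 2]) {
      c("CONSERVED", "TRANSGRESSIVE_UP", "TRANSGRESSIVE_DOWN")
    } else {
      c("ADDITIVITY", "ELD_P1", "ELD_P2", "TRANSGRESSIVE_UP",
        "TRANSGRESSIVE_DOWN")
    }
    w <- pr[compatible]
    cat_f2[i] <- sample(compatible, 1, prob = w / sum(w))
  }
  mu <- cbind(
    P1 = pm[, 1], P2 = pm[, 2],
    F1 = mapply(hybrid_mean, cat_f1, pm[, 1], pm[, 2], lambda,
                MoreArgs = list(delta = delta, generation = "F1")),
    F2 = mapply(hybrid_mean, cat_f2, pm[, 1], pm[, 2], lambda,
                MoreArgs = list(delta = delta, generation = "F2")))
  mpv <- (mu[, "P1"] + mu[, "P2"]) / 2
  m_f1 <- ifelse(mpv > 0 & mu[, "F1"] > 0, log2(mu[, "F1"] / mpv), 0)
  m_f2 <- ifelse(mpv > 0 & mu[, "F2"] > 0, log2(mu[, "F2"] / mpv), 0)
  depths <- params$library_sizes
  counts <- vapply(SAMPLE_LABELS,
                   function(s) draw_counts(mu[, s], depths[[s]],
                                           params$nb_dispersion),
                   numeric(n))
  mirna_ct <- count_table(counts, ids, SAMPLE_LABELS,
                          library_sizes = pmax(depths, colSums(counts)))

  # couple targets to miRNAs that actually move versus the MPV
  n_coupled <- round(params$mirna_coupled_frac * n)
  movers <- which(abs(m_f1) > 0.1)
  coupled <- utils::head(movers, n_coupled)
  lo <- params$targets_per_mirna[1]; hi <- params$targets_per_mirna[2]
  k_tgt <- if (length(coupled)) sample(lo:hi, length(coupled),
                                       replace = TRUE) else integer(0)
  if (sum(k_tgt) > params$n_genes) {
    stop("more coupled targets requested than genes available",
         call. = FALSE)
  }
  gene_ids <- gene_sim$truth$gene_id
  # each adjusted gene belongs to one miRNA so planted couplings do not
  # overwrite each other
  tgt_pool <- sample(gene_ids, sum(k_tgt))
  map <- data.frame(mirna_id = rep(ids[coupled], k_tgt),
                    gene_id = tgt_pool, stringsAsFactors = FALSE)
  gene_truth <- gene_sim$truth
  gmu <- as.matrix(gene_truth[, c("mu_P1", "mu_P2", "mu_F1", "mu_F2")])
  gi <- match(map$gene_id, gene_ids)
  mi <- match(map$mirna_id, ids)
  gene_mpv <- (gmu[gi, 1] + gmu[gi, 2]) / 2
  beta <- params$mirna_coupling_beta
  eps1 <- stats::rnorm(nrow(map), 0, params$mirna_noise_sd)
  eps2 <- stats::rnorm(nrow(map), 0, params$mirna_noise_sd)
  tgt_l2fc_f1 <- -beta * m_f1[mi] + eps1
  tgt_l2fc_f2 <- -beta * m_f2[mi] + eps2
  gene_counts <- gene_sim$counts
  if (beta != 0 && nrow(map)) {
    gmu[gi, "mu_F1"] <- gene_mpv * 2^tgt_l2fc_f1
    gmu[gi, "mu_F2"] <- gene_mpv * 2^tgt_l2fc_f2
    newc <- gene_counts$counts
    newc[gi, "F1"] <- draw_counts(gmu[gi, "mu_F1"], depths[["F1"]],
                                  params$nb_dispersion)
    newc[gi, "F2"] <- draw_counts(gmu[gi, "mu_F2"], depths[["F2"]],
                                  params$nb_dispersion)
    gene_counts <- count_table(newc, gene_counts$gene_ids, SAMPLE_LABELS,
                               library_sizes = pmax(depths, colSums(newc)))
    gene_truth[, c("mu_F1", "mu_F2")] <- gmu[, c("mu_F1", "mu_F2")]
  }
  gene_truth$target_of <- NA_character_
  gene_truth$target_of[gi] <- map$mirna_id
  gene_truth$coupled_l2fc_f1 <- NA_real_
  gene_truth$coupled_l2fc_f1[gi] <- tgt_l2fc_f1
  gene_truth$coupled_l2fc_f2 <- NA_real_
  gene_truth$coupled_l2fc_f2[gi] <- tgt_l2fc_f2
  # decoy links from uncoupled miRNAs keep the map many-to-many without
  # touching any gene mean
  uncoupled <- setdiff(seq_len(n), coupled)
  if (length(uncoupled) >= 2 && params$n_genes >= 2) {
    n_decoy <- min(length(uncoupled), 20L)
    decoy <- data.frame(
      mirna_id = ids[sample(uncoupled, n_decoy, replace = TRUE)],
      gene_id = sample(gene_ids, n_decoy, replace = TRUE),
      stringsAsFactors = FALSE)
    map <- unique(rbind(map, decoy))
  }
  mirna_truth <- data.frame(mirna_id = ids, category_f1 = cat_f1,
                            category_f2 = cat_f2, true_m_f1 = m_f1,
                            true_m_f2 = m_f2,
                            coupled = seq_len(n) %in% coupled,
                            stringsAsFactors = FALSE)
  list(mirna_counts = mirna_ct, target_map = map,
       mirna_truth = mirna_truth, gene_counts = gene_counts,
       gene_truth = gene_truth)
}

#' Write a full simulated dataset to a directory
#'
#' Writes counts.tsv, gene_meta.tsv, mirna_counts.tsv, targets.tsv,
#' truth.tsv, mirna_truth.tsv and params.yaml, the file layout the
#' pipeline's readers expect.
#'
#' @param params a \code{\link{sim_params}}.
#' @param out_dir destination directory (created if needed).
#' @return invisibly, the list of written paths.
#' @export
simulate_to_dir <- function(params, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- simulate_trio(params)
  mir <- simulate_mirna_layer(params, sim)
  paths <- c(counts = file.path(out_dir, "counts.tsv"),
             gene_meta = file.path(out_dir, "gene_meta.tsv"),
             mirna_counts = file.path(out_dir, "mirna_counts.tsv"),
             targets = file.path(out_dir, "targets.tsv"),
             truth = file.path(out_dir, "truth.tsv"),
             mirna_truth = file.path(out_dir, "mirna_truth.tsv"),
             params = file.path(out_dir, "params.yaml"))
  write_count_table(mir$gene_counts, paths[["counts"]])
  meta_out <- data.frame(
    gene_id = sim$meta$gene_id, length_bp = sim$meta$length_bp,
    go_terms = vapply(sim$meta$go_terms, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.table(meta_out, paths[["gene_meta"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_count_table(mir$mirna_counts, paths[["mirna_counts"]])
  utils::write.table(mir$target_map, paths[["targets"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_result_tsv(mir$gene_truth, paths[["truth"]])
  write_result_tsv(mir$mirna_truth, paths[["mirna_truth"]])
  yaml::write_yaml(lapply(unclass(params), function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x),
    paths[["params"]])
  invisible(paths)
}
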