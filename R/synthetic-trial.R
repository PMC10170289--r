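# Synthetic four-arm cohort generator: a normobiotic reference distribution,
# dysbiotic shifts on a taxon subset, and partial reversion under
# intervention. Log-normal latent abundances + multinomial counts, so
# overdispersion emerges from the latent layer and per-taxon effects are
# directly controllable.

#' Specify a synthetic trial design
#'
#' Defaults mirror the four-arm cirrhosis-synbiotic study structure: a
#' healthy reference cohort (n = 50) used to fit the normobiotic model, a
#' held-out healthy test cohort (n = 30), a baseline patient arm
#' (NIP, n = 57), and Placebo (n = 21) / Synbiotic (n = 29) intervention
#' arms.
#'
#' @param n_taxa Number of taxa (default 100).
#' @param n_hc_ref,n_hc_test,n_nip,n_placebo,n_synbiotic Arm sizes.
#' @param shift_fraction Fraction of taxa affected by dysbiosis
#'   (default 0.2).
#' @param shift_magnitude Log-scale effect size delta added to affected
#'   taxa's latent means in the dysbiotic arms (default 1.0); half the
#'   affected taxa shift up ("opportunist-like"), half down
#'   ("beneficial-like").
#' @param reversion Fraction rho of the shift undone in the Synbiotic arm
#'   (default 0.7); the Synbiotic latent shift is `(1 - rho) * delta`.
#' @param depth Expected total counts per sample (default 50000).
#' @param latent_sd Per-sample log-scale noise standard deviation
#'   (default 0.5).
#' @param mean_sd Spread of per-taxon baseline log-means; larger values give
#'   a longer-tailed rank-abundance curve (default 1.5).
#' @param seed Integer seed (default 1).
#' @return A `trial_design` list validated against the constraints above.
#' @export
trial_design <- function(n_taxa = 100, n_hc_ref = 50, n_hc_test = 30,
                         n_nip = 57, n_placebo = 21, n_synbiotic = 29,
                         shift_fraction = 0.2, shift_magnitude = 1.0,
                         reversion = 0.7, depth = 50000,
                         latent_sd = 0.5, mean_sd = 1.5, seed = 1L) {
  sizes <- c(n_hc_ref = n_hc_ref, n_hc_test = n_hc_test, n_nip = n_nip,
             n_placebo = n_placebo, n_synbiotic = n_synbiotic)
  if (any(sizes < 2)) abort("every arm needs at least 2 samples")
  if (n_taxa < 2) abort("`n_taxa` must be >= 2")
  if (shift_fraction <= 0 || shift_fraction > 1) {
    abort("`shift_fraction` must be in (0, 1]")
  }
  if (shift_magnitude < 0) abort("`shift_magnitude` must be >= 0")
  if (reversion < 0 || reversion > 1) abort("`reversion` must be in [0, 1]")
  if (round(shift_fraction * n_taxa) < 2) {
    abort("shift_fraction * n_taxa must be >= 2 (both shift directions needed)")
  }
  structure(list(
    n_taxa = as.integer(n_taxa), sizes = sizes,
    shift_fraction = shift_fraction, shift_magnitude = shift_magnitude,
    reversion = reversion, depth = depth, latent_sd = latent_sd,
    mean_sd = mean_sd, seed = as.integer(seed)
  ), class = "trial_design")
}

sample_arm <- function(mu, shift, n, design, prefix) {
  z <- matrix(stats::rnorm(n * length(mu), mean = rep(mu + shift, each = n),
                           sd = design$latent_sd), nrow = n)
  counts <- t(apply(z, 1, function(zi) {
    p <- exp(zi - max(zi))
    stats::rmultinom(1, size = stats::rpois(1, design$depth), prob = p / sum(p))[, 1]
  }))
  rownames(counts) <- sprintf("%s_%03d", prefix, seq_len(n))
  colnames(counts) <- names(mu)
  as_abund_tbl(counts, state = "raw")
}

#' Generate a synthetic four-arm trial
#'
#' Per-taxon baseline latent log-means are drawn from a normal with sd
#' `mean_sd` (a long-tailed rank-abundance curve after exponentiation).
#' The dysbiotic arms (NIP, Placebo) add a signed `shift_magnitude` to the
#' latent means of the affected taxa — half up, half down; the Synbiotic arm
#' adds `(1 - reversion) * shift_magnitude`. Per-sample counts are
#' multinomial draws (total ~ Poisson(`depth`)) from the softmax of the
#' latent values. Identical designs produce identical output.
#'
#' @param design A [trial_design()] object.
#' @return A `synthetic_trial` list: `tables` (named list of raw count
#'   tibbles per arm: `hc_ref`, `hc_test`, `nip`, `placebo`, `synbiotic`),
#'   `metadata` (tibble mapping every sample to its arm label: HC_ref,
#'   HC_test, NIP, Placebo, Synbiotic), and `truth` (tibble of affected taxa
#'   with their signed latent shift).
#' @export
generate_trial <- function(design) {
  if (!inherits(design, "trial_design")) abort("`design` must come from trial_design()")
  withr::with_seed(design$seed, {
    mu <- stats::rnorm(design$n_taxa, 0, design$mean_sd)
    names(mu) <- sprintf("taxon_%03d", seq_len(design$n_taxa))
    m_aff <- round(design$shift_fraction * design$n_taxa)
    affected <- sample(names(mu), m_aff)
    n_up <- ceiling(m_aff / 2)
    delta <- stats::setNames(rep(0, design$n_taxa), names(mu))
    delta[affected[seq_len(n_up)]] <- design$shift_magnitude
    delta[affected[seq.int(n_up + 1, length.out = m_aff - n_up)]] <-
      -design$shift_magnitude
    no_shift <- delta * 0
    tables <- list(
      hc_ref = sample_arm(mu, no_shift, design$sizes[["n_hc_ref"]], design, "HCR"),
      hc_test = sample_arm(mu, no_shift, design$sizes[["n_hc_test"]], design, "HCT"),
      nip = sample_arm(mu, delta, design$sizes[["n_nip"]], design, "NIP"),
      placebo = sample_arm(mu, delta, design$sizes[["n_placebo"]], design, "PLA"),
      synbiotic = sample_arm(mu, (1 - design$reversion) * delta,
                             design$sizes[["n_synbiotic"]], design, "SYN")
    )
  })
  labels <- c(hc_ref = "HC_ref", hc_test = "HC_test", nip = "NIP",
              placebo = "Placebo", synbiotic = "Synbiotic")
  metadata <- purrr::map_dfr(names(tables), function(arm) {
    tibble(sample_id = tables[[arm]]$sample_id, group = labels[[arm]])
  })
  truth <- tibble(taxon = affected,
                  delta = unname(delta[affected]))
  structure(list(tables = tables, metadata = metadata, truth = truth,
                 design = design), class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  sizes <- vapply(x$tables, nrow, 1L)
  cat(sprintf(
    "Synthetic four-arm trial: %d taxa; arms [%s]; %d shifted taxa (delta = %.2g, reversion = %.2g)\n",
    x$design$n_taxa,
    paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "),
    nrow(x$truth), x$design$shift_magnitude, x$design$reversion))
  invisible(x)
}

#' Generate metabolite profiles correlated with chosen taxa
#'
#' Metabolite columns are log-normal noise except for declared (taxon,
#' metabolite) pairs, which are generated at a target Spearman correlation
#' through a Gaussian copula: the taxon's relative abundances are mapped to
#' normal scores, mixed with independent noise at the Pearson correlation
#' `2 sin(pi * rho / 6)` that induces the requested rank correlation, and
#' exponentiated to keep values positive.
#'
#' @param trial A `synthetic_trial` object; samples from all arms are used.
#' @param n_metabolites Number of metabolite columns.
#' @param linked_pairs Tibble (or data frame) with columns `taxon`,
#'   `metabolite` (index in `1..n_metabolites` or name `metab_###`), and
#'   `rho` (target Spearman, `|rho| < 1`).
#' @param seed Integer seed.
#' @return Tibble of positive metabolite values with one row per trial
#'   sample.
#' @export
generate_correlated_metabolites <- function(trial, n_metabolites,
                                            linked_pairs = NULL, seed = 1L) {
  if (!inherits(trial, "synthetic_trial")) abort("`trial` must come from generate_trial()")
  counts <- do.call(rbind, lapply(trial$tables, abund_matrix))
  rel <- counts / rowSums(counts)
  n <- nrow(rel)
  met_ids <- sprintf("metab_%03d", seq_len(n_metabolites))
  if (!is.null(linked_pairs) && nrow(linked_pairs) > 0) {
    if (!all(c("taxon", "metabolite", "rho") %in% names(linked_pairs))) {
      abort("`linked_pairs` needs columns taxon, metabolite, rho")
    }
    if (any(abs(linked_pairs$rho) >= 1)) abort("|target rho| must be < 1")
    bad <- setdiff(linked_pairs$taxon, colnames(rel))
    if (length(bad) > 0) {
      abort(sprintf("unknown taxon/taxa in linked_pairs: %s",
                    paste(bad, collapse = ", ")))
    }
  }
  withr::with_seed(as.integer(seed), {
    z <- matrix(stats::rnorm(n * n_metabolites), nrow = n,
                dimnames = list(rownames(rel), met_ids))
    if (!is.null(linked_pairs) && nrow(linked_pairs) > 0) {
      for (i in seq_len(nrow(linked_pairs))) {
        met <- linked_pairs$metabolite[i]
        j <- if (is.numeric(met)) as.integer(met) else match(met, met_ids)
        if (is.na(j) || j < 1 || j > n_metabolites) {
          abort(sprintf("metabolite '%s' out of range", as.character(met)))
        }
        r <- 2 * sin(pi * linked_pairs$rho[i] / 6)
        u <- rank(rel[, linked_pairs$taxon[i]]) / (n + 1)
        z[, j] <- r * stats::qnorm(u) + sqrt(1 - r^2) * z[, j]
      }
    }
    as_abund_tbl(exp(z), state = "raw")
  })
}

#' Run the full Dysbiosis Index pipeline on abundance tables
#'
#' Convenience wrapper tying the stages together: closes the reference table
#' to relative abundances, applies the prevalence filter and log-ratio
#' transform, fits the normobiotic model on the healthy reference arm, and
#' scores every other table with the reference's feature set, pseudocount and
#' transform.
#'
#' @param reference Raw abundance tibble of healthy reference samples.
#' @param samples Named list of raw abundance tibbles to score.
#' @param transform `"clr"` (default) or `"log-relative"`.
#' @param min_prevalence Reference prevalence filter (default 0.1).
#' @param variance_target,alpha,autoscale Passed to
#'   [fit_reference_model()].
#' @param combine DI combination rule, passed to [score_samples()].
#' @return List with `model` (`normo_ref`) and `scores` (one `di_scores`
#'   tibble combining all scored tables).
#' @export
di_pipeline <- function(reference, samples, transform = "clr",
                        min_prevalence = 0.1, variance_target = 0.9,
                        alpha = 0.05, autoscale = FALSE, combine = "mean") {
  ref_rel <- prevalence_filter(to_relative_abundance(reference),
                               min_prevalence = min_prevalence)
  ref_tr <- transform_abundance(ref_rel, method = transform)
  pc <- attr(ref_tr, "pseudocount")
  feats <- setdiff(names(ref_rel), "sample_id")
  model <- fit_reference_model(ref_tr, variance_target = variance_target,
                               alpha = alpha, autoscale = autoscale)
  scores <- purrr::map(samples, function(tb) {
    miss <- setdiff(feats, names(tb))
    if (length(miss) > 0) {
      abort(sprintf("sample table lacks reference feature(s): %s",
                    paste(utils::head(miss, 5), collapse = ", ")))
    }
    # restrict to the reference feature set, then close, so the composition
    # is expressed on the model's sub-composition
    rel <- to_relative_abundance(tb[c("sample_id", feats)])
    tr <- transform_abundance(rel, method = transform, pseudocount = pc)
    score_samples(model, tr, combine = combine)
  })
  combined <- dplyr::bind_rows(scores)
  attr(combined, "t2_limit") <- model$t2_limit
  attr(combined, "q_limit") <- model$q_limit
  attr(combined, "alpha") <- model$alpha
  class(combined) <- c("di_scores", class(combined))
  list(model = model, scores = combined)
}
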