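# Synthetic assay panels with planted ground truth. The generator emits
# raw measurement tables in the exact schema consumed by
# quantify_assays(), so the whole pipeline can be exercised and its
# ability to recover known top performers measured.

#' Specify a synthetic assay panel
#'
#' Distributional defaults emulate a drought-screening bench panel:
#' uniform colony geometry (colony 3-10 mm, halo extension 0-15 mm),
#' absorbance pairs with a fixed reference and a uniform color-shift
#' fraction, log-normal IAA / NH3 / EPS concentrations whose ranges bracket
#' the values seen across drought-tolerant grapevine isolates (IAA roughly
#' 8-47 ug/mL), and a logistic-growth OD600 endpoint under PEG with
#' Gaussian read noise (sd 0.02). `n_planted_top` strains are planted as
#' across-the-board top performers: every quantitative trait drawn from the
#' top decile of its distribution and all qualitative traits positive.
#'
#' @param n_strains Number of strains in the panel.
#' @param seed Integer seed; the same spec generates byte-identical tables.
#' @param replicates Replicates per assay (default 3).
#' @param n_planted_top Number of planted top performers (default 0).
#' @param p_antagonism,p_limited Per-pair probabilities for the companion
#'   compatibility matrix (defaults 0.1 and 0.05).
#' @param noise_od Gaussian SD of OD600 readings (default 0.02).
#' @return A `panel_spec` list.
#' @export
panel_spec <- function(n_strains = 50, seed = 1, replicates = 3,
                       n_planted_top = 0, p_antagonism = 0.1,
                       p_limited = 0.05, noise_od = 0.02) {
  if (n_planted_top > n_strains) {
    rr_stop("n_planted_top cannot exceed n_strains", "rr_spec_error")
  }
  if (p_antagonism < 0 || p_limited < 0 || p_antagonism + p_limited > 1) {
    rr_stop("interaction probabilities must be in [0, 1] and sum <= 1",
            "rr_spec_error")
  }
  if (replicates < 1 || n_strains < 1) {
    rr_stop("n_strains and replicates must be positive", "rr_spec_error")
  }
  structure(list(n_strains = n_strains, seed = seed, replicates = replicates,
                 n_planted_top = n_planted_top, p_antagonism = p_antagonism,
                 p_limited = p_limited, noise_od = noise_od),
            class = "panel_spec")
}

# Draw n values from a log-normal; planted strains draw their underlying
# quantile from [0.9, 1) so they sit in the top decile of the distribution.
rlnorm_planted <- function(n, planted, meanlog, sdlog) {
  q <- stats::runif(n)
  q[planted] <- stats::runif(sum(planted), 0.9, 0.999)
  stats::qlnorm(q, meanlog, sdlog)
}

#' Generate a synthetic raw assay panel
#'
#' Emits replicate-level raw tables (halo diameters, absorbance pairs,
#' colorimetric readings plus standard-curve points, gravimetric EPS,
#' OD600 growth series under 0/12/24/32% PEG, qualitative flags) in the
#' [quantify_assays()] input schema, together with a truth record naming
#' the planted top performers and their per-trait quantiles.
#'
#' @param spec A [panel_spec()].
#' @return List with `raw` (named list of raw tables), `truth` (list with
#'   `planted` ids and `quantiles` data frame) and `strain_ids`.
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed)

  n <- spec$n_strains
  reps <- spec$replicates
  ids <- sprintf("SYN%03d", seq_len(n))
  planted_ids <- if (spec$n_planted_top > 0) {
    sort(sample(ids, spec$n_planted_top))
  } else character(0)
  planted <- ids %in% planted_ids

  quantile_of <- function(q) ifelse(planted, stats::runif(n, 0.9, 0.999), q)

  rep_noise <- function(mu, sd) {
    # replicate-level noise around a strain-level true value
    stats::rnorm(length(mu), mu, sd)
  }

  # Halo assays: colony 3-10 mm; halo extension quantile-driven, 0-15 mm.
  halo <- do.call(rbind, lapply(c("PS_plate", "KS"), function(a) {
    colony <- stats::runif(n, 3, 10)
    q <- quantile_of(stats::runif(n))
    ext <- 15 * q
    do.call(rbind, lapply(seq_len(reps), function(r) {
      data.frame(strain_id = ids, assay = a, replicate = r,
                 colony_diameter = pmax(1, rep_noise(colony, 0.2)),
                 total_diameter = NA_real_, stringsAsFactors = FALSE) -> d
      d$total_diameter <- d$colony_diameter + pmax(0, rep_noise(ext, 0.3))
      d
    }))
  }))

  # Absorbance pairs: fixed reference, sample = Ar * (1 - shift), shift in
  # [0, 0.95] quantile-driven (high shift = strong producer).
  absb <- do.call(rbind, lapply(c("SID", "PS_broth"), function(a) {
    ar <- if (a == "SID") 0.80 else 1.00
    q <- quantile_of(stats::runif(n))
    shift <- 0.95 * q
    do.call(rbind, lapply(seq_len(reps), function(r) {
      data.frame(strain_id = ids, assay = a, replicate = r,
                 reference_abs = ar,
                 sample_abs = pmin(ar, pmax(0, rep_noise(ar * (1 - shift), 0.01))),
                 stringsAsFactors = FALSE)
    }))
  }))

  # Colorimetric concentrations via a linear instrument response.
  curves <- list(NH3 = c(slope = 0.004, intercept = 0.03),
                 IAA = c(slope = 0.02, intercept = 0.05))
  lognorm <- list(NH3 = c(meanlog = log(40), sdlog = 0.8),
                  IAA = c(meanlog = log(15), sdlog = 0.6))
  standards <- do.call(rbind, lapply(names(curves), function(a) {
    conc <- if (a == "NH3") seq(0, 200, by = 40) else seq(0, 50, by = 10)
    data.frame(analyte = a, concentration = conc,
               absorbance = curves[[a]]["slope"] * conc + curves[[a]]["intercept"],
               stringsAsFactors = FALSE)
  }))
  colorimetric <- do.call(rbind, lapply(names(curves), function(a) {
    p <- lognorm[[a]]
    true <- rlnorm_planted(n, planted, p["meanlog"], p["sdlog"])
    do.call(rbind, lapply(seq_len(reps), function(r) {
      ab <- curves[[a]]["slope"] * rep_noise(true, 0.05 * true) +
        curves[[a]]["intercept"]
      data.frame(strain_id = ids, analyte = a, condition = "optimal",
                 replicate = r, absorbance = pmax(0, ab),
                 stringsAsFactors = FALSE)
    }))
  }))

  # Gravimetric EPS, g/L.
  eps_true <- rlnorm_planted(n, planted, log(0.2), 0.8)
  eps <- do.call(rbind, lapply(seq_len(reps), function(r) {
    data.frame(strain_id = ids, condition = "optimal", replicate = r,
               eps_g_l = pmax(0, rep_noise(eps_true, 0.05 * eps_true)),
               stringsAsFactors = FALSE)
  }))

  # OD600 growth under PEG: logistic endpoint K scaled down with PEG dose;
  # planted strains have K in the top decile so they pass the pre-screen.
  k0 <- ifelse(planted, stats::runif(n, 0.92, 1.0), stats::runif(n, 0.3, 1.0))
  peg_levels <- c(0, 12, 24, 32)
  dose_factor <- c(1.0, 0.9, 0.78, 0.55)
  growth <- do.call(rbind, lapply(seq_along(peg_levels), function(pi) {
    k <- k0 * dose_factor[pi]
    do.call(rbind, lapply(c(12, 24, 48), function(t) {
      frac <- 1 / (1 + exp(-0.25 * (t - 18)))  # logistic time course
      do.call(rbind, lapply(seq_len(reps), function(r) {
        data.frame(strain_id = ids, peg_percent = peg_levels[pi],
                   timepoint_h = t, replicate = r,
                   od600 = pmax(0, stats::rnorm(n, k * frac, spec$noise_od)),
                   stringsAsFactors = FALSE)
      }))
    }))
  }))

  # Qualitative traits: planted always positive.
  qual <- do.call(rbind, lapply(c("NH4", "BF"), function(tr) {
    pos <- stats::runif(n) < 0.5
    pos[planted] <- TRUE
    data.frame(strain_id = ids, trait = tr, positive = pos,
               stringsAsFactors = FALSE)
  }))

  # DT endpoint (24% PEG, 48 h) implied by k0 * 0.78 * logistic(48h) ~ k0*0.78
  truth <- list(
    planted = planted_ids,
    quantiles = data.frame(strain_id = ids, planted = planted,
                           k0 = k0, stringsAsFactors = FALSE)
  )
  list(raw = list(halo = halo, absorbance = absb,
                  colorimetric = colorimetric, standards = standards,
                  eps = eps, growth = growth, qualitative = qual),
       truth = truth, strain_ids = ids)
}

#' Generate a random pairwise compatibility matrix
#'
#' Each unordered strain pair is independently antagonistic (probability
#' `p_antagonism`), limited-growth (`p_limited`) or compatible.
#'
#' @param strain_ids Character vector of strain ids.
#' @param p_antagonism,p_limited Outcome probabilities (sum <= 1).
#' @param seed Integer seed.
#' @return A `compat_matrix` covering every unordered pair.
#' @export
generate_compatibility <- function(strain_ids, p_antagonism = 0.1,
                                   p_limited = 0.05, seed = 1) {
  if (p_antagonism < 0 || p_limited < 0 || p_antagonism + p_limited > 1) {
    rr_stop("probabilities must be in [0, 1] and sum <= 1", "rr_spec_error")
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  ids <- sort(unique(strain_ids))
  if (length(ids) < 2) {
    return(compatibility_matrix(data.frame(strain_a = character(),
                                           strain_b = character(),
                                           outcome = character())))
  }
  pr <- utils::combn(ids, 2)
  u <- stats::runif(ncol(pr))
  outcome <- ifelse(u < p_antagonism, "antagonistic",
                    ifelse(u < p_antagonism + p_limited, "limited_growth",
                           "compatible"))
  compatibility_matrix(data.frame(strain_a = pr[1, ], strain_b = pr[2, ],
                                  outcome = outcome,
                                  stringsAsFactors = FALSE))
}

# Save / restore .Random.seed so generators do not perturb the caller's
# random stream.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}
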