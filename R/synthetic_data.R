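# Seeded generator of scan tables, bracketed sequences, labeled-standard
# series and degradation scenarios with the statistical structure the
# pipeline assumes: Poisson ion statistics at the AGC-controlled fill,
# stochastic isotopologue abundances implied by true delta shifts, a
# delta-space instrument response, and slow multiplicative spray drift that
# affects all isotopologues equally (and therefore cancels in ratios).

#' Simulation configuration
#'
#' @param agc_target Ions per fill (instrument settings 1.0e6 / 1.5e6 /
#'   3.0e6; default 3.0e6, the setting used for all final measurements).
#' @param transfer_efficiency Fraction of the AGC fill detected as the two
#'   fragments (precursor transmission x fragmentation yield; default 0.5 -
#'   an order-of-magnitude choice, not an instrument-reported value).
#' @param fragment_split Fraction of detected fragment ions that are F92.
#' @param scan_period_s Seconds per stored spectrum (10 microscans at
#'   R = 90,000; default 2 s, so a 15-min window holds ~450 scans).
#' @param true_deltas Named numeric vector of true delta shifts vs the
#'   working reference, per mil, keyed `"fragment.element"` (e.g.
#'   `c(F99.N = 25)`); missing keys are 0.
#' @param response_slope,response_intercept Instrument response applied in
#'   delta space per key (observed = intercept + slope x true); named
#'   vectors with default 1 and 0.
#' @param drift_rsd Relative SD of the slow multiplicative ion-current
#'   drift over a run (spray stability criterion < 0.08; default 0.05).
#' @param noise_floor Constant peak noise used when inverting the
#'   ion-count relation into intensities.
#' @param resolution,microscans,charge Per-scan instrument fields written
#'   into the table (defaults 90,000, 10, 1).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(agc_target = 3e6, transfer_efficiency = 0.5,
                       fragment_split = 0.5, scan_period_s = 2,
                       true_deltas = numeric(0),
                       response_slope = numeric(0),
                       response_intercept = numeric(0),
                       drift_rsd = 0.05, noise_floor = 1000,
                       resolution = 90000, microscans = 10, charge = 1L) {
  stopifnot(agc_target > 0, transfer_efficiency > 0, transfer_efficiency <= 1,
            fragment_split > 0, fragment_split < 1, scan_period_s > 0,
            drift_rsd >= 0, noise_floor > 0)
  structure(
    list(agc_target = agc_target, transfer_efficiency = transfer_efficiency,
         fragment_split = fragment_split, scan_period_s = scan_period_s,
         true_deltas = true_deltas, response_slope = response_slope,
         response_intercept = response_intercept, drift_rsd = drift_rsd,
         noise_floor = noise_floor, resolution = resolution,
         microscans = microscans, charge = as.integer(charge)),
    class = "sim_config"
  )
}

key_get <- function(v, key, default) {
  if (key %in% names(v)) unname(v[[key]]) else default
}

# Observed (response-distorted) delta for a fragment/element key.
observed_delta <- function(config, key) {
  tr <- key_get(config$true_deltas, key, 0)
  key_get(config$response_intercept, key, 0) +
    key_get(config$response_slope, key, 1) * tr
}

#' Simulate a scan-level isotopologue table
#'
#' Generates one continuous acquisition: per scan, the expected number of
#' detected fragment ions is `agc_target x transfer_efficiency`, modulated
#' by a multiplicative drift random walk, split across F92/F99 and across
#' each fragment's monitored isotopologues with stochastic-model abundances
#' implied by the configured true deltas (after the delta-space instrument
#' response). Counts are drawn Poisson and converted to intensities by
#' inverting the ion-count relation at constant peak noise, so that
#' [ions_per_scan()] on a simulated row returns the drawn count to machine
#' precision.
#'
#' @param config A [sim_config()].
#' @param duration_min Acquisition length, minutes.
#' @param t_offset_min Timeline offset of the first scan, minutes.
#' @param scan_offset Scan-number offset (scan indices are 1-based).
#' @param source_id Source tag written into the table.
#' @param catalog Isotopologue catalog.
#' @param seed Optional integer; when given, `set.seed(seed)` is applied.
#' @return List with `scans` (a scan table) and `truth` (the generating
#'   parameters: config, duration, seed).
#' @export
simulate_scan_table <- function(config = sim_config(), duration_min = 15,
                                t_offset_min = 0, scan_offset = 0L,
                                source_id = "sim", catalog = smx_catalog(),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_scans <- floor(duration_min * 60 / config$scan_period_s)
  if (n_scans < 1L) stop("duration too short for one scan")
  times <- t_offset_min + (seq_len(n_scans) - 1L) * config$scan_period_s / 60

  # slow multiplicative drift, common to all isotopologues
  drift <- if (config$drift_rsd > 0) {
    step <- config$drift_rsd * sqrt(3 / n_scans)
    exp(cumsum(stats::rnorm(n_scans, 0, step)))
  } else rep(1, n_scans)

  total <- config$agc_target * config$transfer_efficiency * drift
  frag_frac <- c(F92 = config$fragment_split, F99 = 1 - config$fragment_split)

  pairs <- catalog_pairs(catalog)
  rows <- list()
  for (frag in names(frag_frac)) {
    base_spec <- catalog[[frag]]
    pp <- pairs[pairs$fragment == frag, , drop = FALSE]
    w <- c(1, vapply(seq_len(nrow(pp)), function(i) {
      r_nat <- natural_isotope_ratio(pp$element[i])
      dobs <- observed_delta(config, paste(frag, pp$element[i], sep = "."))
      stochastic_isotopologue_ratio(base_spec$formula, pp$element[i],
                                    r_nat * (1 + dobs / 1000))
    }, numeric(1)))
    labels <- c(frag, pp$label)
    w <- w / sum(w)
    expected_frag <- total * frag_frac[[frag]]
    if (any(expected_frag <= 0)) stop("expected ion count <= 0")
    for (i in seq_along(labels)) {
      counts <- stats::rpois(n_scans, expected_frag * w[i])
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = source_id,
        scan = scan_offset + seq_len(n_scans),
        time.min = times,
        isotopolog = labels[i],
        n_io = counts,
        stringsAsFactors = FALSE)
    }
  }
  scans <- do.call(rbind, rows)

  # invert the ion-count relation at constant peak noise
  scale <- (3 / config$charge) *
    sqrt(240000 / config$resolution) * sqrt(config$microscans)
  scans$intensity <- scans$n_io * config$noise_floor / scale
  scans$peakNoise <- config$noise_floor
  scans$resolution <- config$resolution
  scans$microscans <- config$microscans
  scans$charge <- config$charge
  scans$n_io <- NULL
  scans <- scans[order(scans$time.min, scans$isotopolog), , drop = FALSE]
  rownames(scans) <- NULL

  list(scans = scans,
       truth = list(config = config, duration_min = duration_min,
                    t_offset_min = t_offset_min, seed = seed))
}

#' Simulate a bracketed measurement sequence
#'
#' Builds one timeline of alternating reference/sample blocks (reference
#' first, so `n_blocks = 9` gives the five-reference / four-sample
#' pattern of an 18-min-block LC run), generating each block from the
#' reference or sample true-delta configuration.
#'
#' @param sample_deltas Named true delta shifts of the sample, per mil
#'   (keys `"fragment.element"`).
#' @param reference_deltas Same for the reference (default all 0: the
#'   working reference defines the zero of the shift scale).
#' @param config A [sim_config()] shared by both roles.
#' @param run_cfg A [run_config()] supplying the block duration.
#' @param n_blocks Number of blocks (>= 3, odd to end on a reference).
#' @param seed Optional integer seed.
#' @return List with `scans` (one scan table spanning all blocks), `blocks`
#'   (the role table), and `truth`.
#' @export
simulate_bracketed_sequence <- function(sample_deltas = numeric(0),
                                        reference_deltas = numeric(0),
                                        config = sim_config(),
                                        run_cfg = run_config(),
                                        n_blocks = 9L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_blocks >= 3L)
  d <- run_cfg$block_duration_min
  per_block <- floor(d * 60 / config$scan_period_s)
  out <- vector("list", n_blocks)
  for (k in seq_len(n_blocks) - 1L) {
    role <- if (k %% 2L == 0L) "reference" else "sample"
    cfg_k <- config
    cfg_k$true_deltas <- if (role == "sample") sample_deltas
                         else reference_deltas
    out[[k + 1L]] <- simulate_scan_table(
      cfg_k, duration_min = d, t_offset_min = k * d,
      scan_offset = k * per_block, source_id = "sim_sequence",
      seed = NULL)$scans
  }
  scans <- do.call(rbind, out)
  rownames(scans) <- NULL
  roles <- ifelse((seq_len(n_blocks) - 1L) %% 2L == 0L,
                  "reference", "sample")
  list(scans = scans,
       blocks = data.frame(index = seq_len(n_blocks), role = roles),
       truth = list(sample_deltas = sample_deltas,
                    reference_deltas = reference_deltas,
                    config = config, n_blocks = n_blocks, seed = seed))
}

#' Simulate a labeled-standard series with EA-IRMS characterization
#'
#' For each labeled position (inside one fragment) and each spike target,
#' the true bulk shift follows from first-order mass balance: a target
#' enrichment of x per mil in the labeled fragment dilutes to
#' `x * n_element(fragment) / n_element(molecule)` at the bulk level (the
#' inverse of [fragment_calc_from_bulk()], i.e. [bulk_from_fragments()]
#' with the other fragments at 0). EA-IRMS replicate measurements are then
#' drawn around the true bulk shift with the homogeneity-level noise. For a
#' fragment holding a single atom of the element (e.g. F92 nitrogen) the
#' fragment and position enrichments coincide.
#'
#' @param positions List of `list(fragment =, element =)` labeled
#'   positions.
#' @param spike_targets Target enrichments of the labeled fragment per
#'   standard in the series, per mil (default the 50 / 100 / 200
#'   preparation targets).
#' @param ea_sd EA-IRMS replicate SD, per mil (default 0.3, the
#'   homogeneity criterion).
#' @param n_replicates EA-IRMS replicates per standard (default 5).
#' @param molecule A [molecule_def()].
#' @param seed Optional integer seed.
#' @return List with `standards` (standard_id, fragment, element,
#'   position_target, delta_bulk_shift as the replicate mean, sd,
#'   n_replicates, delta_calc) and `ea_records` (replicate-level draws).
#' @export
simulate_standard_series <- function(positions,
                                     spike_targets = c(50, 100, 200),
                                     ea_sd = 0.3, n_replicates = 5L,
                                     molecule = smx_molecule(),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(spike_targets > 0), ea_sd >= 0)
  std_rows <- list(); rep_rows <- list()
  for (p in seq_along(positions)) {
    pos <- positions[[p]]
    if (frag_count(molecule, pos$fragment, pos$element) == 0L)
      stop("no ", pos$element, " atom in fragment ", pos$fragment)
    frag_deltas <- stats::setNames(
      rep(0, length(molecule$fragments)), names(molecule$fragments))
    frag_deltas <- frag_deltas[vapply(names(frag_deltas), frag_count,
                                      numeric(1), molecule = molecule,
                                      element = pos$element) > 0]
    for (s in seq_along(spike_targets)) {
      fd <- frag_deltas
      fd[pos$fragment] <- spike_targets[s]
      true_bulk <- bulk_from_fragments(fd, molecule, pos$element)
      reps <- stats::rnorm(n_replicates, true_bulk, ea_sd)
      id <- paste0(LETTERS[p], s)
      std_rows[[length(std_rows) + 1L]] <- data.frame(
        standard_id = id, fragment = pos$fragment, element = pos$element,
        position_target = spike_targets[s],
        delta_bulk_shift = mean(reps), sd = ea_sd,
        n_replicates = n_replicates,
        delta_calc = fragment_calc_from_bulk(mean(reps), molecule,
                                             pos$fragment, pos$element),
        stringsAsFactors = FALSE)
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        standard_id = id, element = pos$element, replicate = seq_along(reps),
        delta_bulk = reps, stringsAsFactors = FALSE)
    }
  }
  list(standards = do.call(rbind, std_rows),
       ea_records = do.call(rbind, rep_rows))
}

#' Closed-form Rayleigh delta shift
#'
#' For a reaction with enrichment factor epsilon (per mil) and remaining
#' substrate fraction f, the substrate delta shift is
#' \eqn{\Delta\delta = \epsilon \ln f} (first-order in delta space); a
#' normal (negative) epsilon enriches the residual substrate as f falls.
#'
#' @param epsilon Enrichment factor, per mil.
#' @param f Remaining fraction in (0, 1].
#' @return Delta shift, per mil.
#' @export
#' @examples
#' rayleigh_shift(-10, 0.5)  # ~6.93
rayleigh_shift <- function(epsilon, f) {
  stopifnot(all(f > 0), all(f <= 1))
  epsilon * log(f)
}

#' Simulate a degradation time series of bracketed sequences
#'
#' One bracketed sequence per timepoint, with the true deltas following the
#' scenario trajectories; fragment/element keys absent from the scenario
#' (unreactive positions) stay at their initial value.
#'
#' @param scenario List with `timepoints` (vector) and `trajectories`
#'   (named list keyed `"fragment.element"`, each a numeric vector of true
#'   deltas per timepoint, per mil). Alternatively supply `epsilon` and
#'   `remaining_f` per key to derive a trajectory via [rayleigh_shift()].
#' @param config A [sim_config()].
#' @param run_cfg A [run_config()].
#' @param n_blocks Blocks per sequence (default 9).
#' @param seed Optional integer seed (per-timepoint streams derive from
#'   it).
#' @return List of per-timepoint lists: `timepoint`, `scans`, `truth`.
#' @export
simulate_degradation <- function(scenario, config = sim_config(),
                                 run_cfg = run_config(), n_blocks = 9L,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tp <- scenario$timepoints
  traj <- scenario$trajectories
  if (is.null(traj) && !is.null(scenario$epsilon)) {
    traj <- lapply(names(scenario$epsilon), function(key)
      rayleigh_shift(scenario$epsilon[[key]], scenario$remaining_f))
    names(traj) <- names(scenario$epsilon)
  }
  stopifnot(!is.null(traj),
            all(vapply(traj, length, integer(1)) == length(tp)),
            all(vapply(traj, function(x) all(is.finite(x)), logical(1))))
  lapply(seq_along(tp), function(i) {
    deltas <- vapply(traj, `[[`, numeric(1), i)
    sim <- simulate_bracketed_sequence(
      sample_deltas = deltas, config = config, run_cfg = run_cfg,
      n_blocks = n_blocks, seed = NULL)
    list(timepoint = tp[i], scans = sim$scans, truth = sim$truth)
  })
}
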