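#' Synthetic deep-water trawl survey with known ground truth
#'
#' Generates a species pool with Gaussian depth niches and trait vectors
#' bounded by the packaged reference trait table, then simulates haul-level
#' survey tables (Poisson catches around the closed-form depth response,
#' truncated-lognormal individual lengths, mixed length types) so that every
#' downstream stage of the pipeline can be tested against closed-form
#' expectations.
#'
#' @name synthetic_survey
NULL

.guild_levels <- c("benthic", "benthic_high", "benthic_low",
                   "benthic_suspension", "pelagic", "pelagic_high", "unknown")

#' Generate a synthetic species pool
#'
#' Trait values are drawn inside the empirical column ranges of the packaged
#' reference trait table. Under the default \code{"mid_peak"} structure,
#' trait extremeness follows a Gaussian of the species' depth-niche centre
#' around \code{peak_depth_m}: species whose niches peak near that depth
#' receive trait values pushed towards the edges of the empirical ranges
#' (in a random direction per species and trait), while species living far
#' from it receive near-central values. This plants a known mid-depth
#' maximum in functional richness and size diversity for recovery tests.
#' \code{"random"} draws every trait uniformly within its range.
#'
#' @param n_species Number of species (default 31, the size of the
#'   reference pool).
#' @param guild_mix Named proportions over the seven guild labels
#'   (\code{benthic}, \code{benthic_high}, \code{benthic_low},
#'   \code{benthic_suspension}, \code{pelagic}, \code{pelagic_high},
#'   \code{unknown}); must sum to 1. Defaults to the reference table's
#'   guild frequencies.
#' @param seed Integer seed; identical seeds give identical pools.
#' @param trait_structure \code{"mid_peak"} (default) or \code{"random"}.
#' @param peak_depth_m Depth of planted trait extremeness (default 1150 m,
#'   the midpoint of the survey depth range).
#' @param structure_breadth_m Gaussian breadth of the extremeness profile
#'   (default 200 m).
#' @param depth_range Survey depth range over which niche centres are
#'   spread (default 300-2000 m).
#' @param nontl_fraction Fraction of species whose lengths are reported in
#'   an alternative length type (SL/PAFL/PSCFL) rather than total length
#'   (default 12/31, the reference survey's share of broken-tail species).
#' @return A tibble with one row per species: identifiers, guild, niche
#'   parameters, allometric and length-distribution parameters, reporting
#'   length type and its true conversion factor, and the eight traits.
#' @export
generate_species_pool <- function(n_species = 31, guild_mix = NULL,
                                  seed = NULL,
                                  trait_structure = c("mid_peak", "random"),
                                  peak_depth_m = 1150,
                                  structure_breadth_m = 200,
                                  depth_range = c(300, 2000),
                                  nontl_fraction = 12 / 31) {
  trait_structure <- match.arg(trait_structure)
  if (length(n_species) != 1 || is.na(n_species) || n_species < 1) {
    abort("`n_species` must be a positive count.")
  }
  n_species <- as.integer(n_species)
  ref <- load_reference_traits()
  if (is.null(guild_mix)) {
    guild_mix <- table(factor(ref$guild, levels = .guild_levels))
    guild_mix <- as.numeric(guild_mix) / sum(guild_mix)
    names(guild_mix) <- .guild_levels
  }
  if (is.null(names(guild_mix)) ||
      !all(names(guild_mix) %in% .guild_levels) ||
      any(guild_mix < 0) || abs(sum(guild_mix) - 1) > 1e-9) {
    abort("`guild_mix` must be named proportions over the guild labels summing to 1.")
  }
  if (!is.null(seed)) set.seed(seed)

  span <- diff(depth_range)
  centers <- seq(depth_range[1], depth_range[2], length.out = n_species)
  if (n_species > 1) {
    centers <- pmin(pmax(centers + rnorm(n_species, 0, span / (4 * n_species)),
                         depth_range[1]), depth_range[2])
  }

  # guild counts proportional to the mix, remainder assigned by largest share
  counts <- floor(guild_mix * n_species)
  rem <- n_species - sum(counts)
  if (rem > 0) {
    extra <- order(guild_mix * n_species - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  guilds <- sample(rep(names(counts), counts))

  extremeness <- if (trait_structure == "mid_peak") {
    exp(-(centers - peak_depth_m)^2 / (2 * structure_breadth_m^2))
  } else rep(NA_real_, n_species)

  draw_trait <- function(values) {
    rng <- range(values, na.rm = TRUE)
    mid <- mean(rng); half <- diff(rng) / 2
    if (trait_structure == "random") return(runif(n_species, rng[1], rng[2]))
    # each consecutive depth-ordered pair of species covers both extremes of
    # the trait axis (in random order, independently per trait), so trait
    # extremes stay locally balanced around the planted peak
    dir <- unlist(lapply(seq_len(ceiling(n_species / 2)),
                         function(i) sample(c(-1, 1))))[seq_len(n_species)]
    mid + extremeness * dir * 0.9 * half +
      (1 - extremeness) * runif(n_species, -0.15, 0.15) * half
  }

  cont <- lapply(ref[continuous_trait_columns()], draw_trait)
  ep_tab <- table(ref$eye_position)
  eye_position <- sample(names(ep_tab), n_species, replace = TRUE,
                         prob = as.numeric(ep_tab))

  n_nontl <- round(nontl_fraction * n_species)
  length_type <- rep("TL", n_species)
  conv_factor <- rep(1, n_species)
  if (n_nontl > 0) {
    alt_idx <- sample(n_species, n_nontl)
    length_type[alt_idx] <- sample(c("SL", "PAFL", "PSCFL"), n_nontl,
                                   replace = TRUE)
    conv_factor[alt_idx] <- runif(n_nontl, 1.05, 1.35)
  }

  lw_a <- runif(n_species, 0.005, 0.02)
  lw_b <- runif(n_species, 2.8, 3.2)
  meanlog <- log(0.30 * cont$lmax_cm)
  sdlog <- 0.25
  # abundance-body size scaling (density ~ mass^-3/4), so small-bodied
  # species are numerous and large-bodied ones rare, as in real trawl data
  expected_w <- lw_a * exp(lw_b * meanlog + lw_b^2 * sdlog^2 / 2)
  density <- stats::rlnorm(n_species, log(10), 0.3) *
    (expected_w / stats::median(expected_w))^(-0.75)

  tibble(
    species_id = sprintf("syn_sp%02d", seq_len(n_species)),
    genus = sprintf("syngen%02d", ceiling(seq_len(n_species) / 2)),
    guild = guilds,
    niche_center_m = centers,
    niche_breadth_m = runif(n_species, 90, 120),
    peak_density = density,
    lw_a = lw_a,
    lw_b = lw_b,
    rel_head = cont$rel_head,
    aspect_ratio = cont$aspect_ratio,
    rel_eye = cont$rel_eye,
    eye_position = eye_position,
    mouth_angle = cont$mouth_angle,
    rel_sam = pmax(cont$rel_sam, 0),
    rel_gape = cont$rel_gape,
    lmax_cm = cont$lmax_cm,
    length_meanlog = meanlog,
    length_sdlog = sdlog,
    length_type = length_type,
    conv_factor = conv_factor
  )
}

# lognormal lengths truncated at lmax via inverse-CDF sampling
rtrunc_lnorm <- function(n, meanlog, sdlog, upper) {
  u <- runif(n) * plnorm(upper, meanlog, sdlog)
  qlnorm(u, meanlog, sdlog)
}

#' Simulate a haul-level survey from a species pool
#'
#' Each depth-grid point becomes a sampling site assigned to an ICES
#' rectangle; sites are revisited in one or more survey years (the number of
#' repeats is 1 + a Poisson draw). The expected catch of species s in a haul
#' of duration t minutes at depth z is \eqn{t/60 \cdot \rho_s \cdot
#' \exp(-(z - c_s)^2 / (2 b_s^2))} (peak density \eqn{\rho_s}, niche centre
#' \eqn{c_s}, breadth \eqn{b_s}), realized as a Poisson draw. Individual
#' total lengths are lognormal truncated at the species' L_max; species that
#' report an alternative length type have their lengths divided by the true
#' conversion factor before entering the catch table. Calibration tables of
#' paired lengths (for conversion-factor estimation) and paired
#' length-weight measurements are emitted alongside.
#'
#' @param pool Species pool from [generate_species_pool()].
#' @param n_rectangles Number of ICES rectangles the sites are spread over.
#' @param depth_grid Depths of the sampling sites (default: 80 evenly
#'   spaced depths over the pool's niche range).
#' @param years Survey years available for revisits.
#' @param duration_mean_min,duration_sd_min Haul duration distribution
#'   (normal, truncated to [60, 180]; default centred at 120 min).
#' @param revisit_rate Poisson rate of extra visits per site (default 1.3,
#'   making roughly a quarter of the sites single-haul stations).
#' @param depth_jitter_sd_m SD of the per-haul depth deviation from the
#'   site's nominal depth (default 15 m), mimicking imperfect repositioning
#'   between revisits.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A list of tibbles: \code{hauls}, \code{catch},
#'   \code{conversion_pairs}, \code{lw_pairs}, and \code{sites} (the
#'   planned depth of each site, for recovery tests).
#' @export
simulate_survey <- function(pool, n_rectangles = 20, depth_grid = NULL,
                            years = c(1998, 2000, 2002, 2004:2009, 2011:2013),
                            duration_mean_min = 120, duration_sd_min = 10,
                            revisit_rate = 1.3, depth_jitter_sd_m = 15,
                            seed = NULL) {
  pool <- as_tibble(pool)
  if (nrow(pool) == 0) abort("`pool` must contain at least one species.")
  if (length(years) == 0) abort("`years` must be non-empty.")
  if (is.null(depth_grid)) {
    depth_grid <- seq(min(pool$niche_center_m), max(pool$niche_center_m),
                      length.out = 80)
  }
  if (length(depth_grid) == 0) abort("`depth_grid` must be non-empty.")
  if (!is.null(seed)) set.seed(seed)

  n_sites <- length(depth_grid)
  sites <- tibble(
    site = seq_len(n_sites),
    depth_m = as.numeric(depth_grid),
    ices_rectangle = sprintf("R%02d", rep_len(seq_len(n_rectangles), n_sites)))

  n_visits <- pmin(1 + rpois(n_sites, revisit_rate), length(years))
  hauls <- sites |>
    mutate(n_visits = n_visits) |>
    rowwise() |>
    mutate(yrs = list(sort(sample(years, .data$n_visits)))) |>
    ungroup() |>
    tidyr::unnest_longer("yrs", values_to = "year") |>
    mutate(
      haul_id = sprintf("H%04d", row_number()),
      depth_m = pmax(.data$depth_m +
                       rnorm(n(), 0, depth_jitter_sd_m), 10),
      duration_min = pmin(pmax(rnorm(n(), duration_mean_min,
                                     duration_sd_min), 60), 180)) |>
    select("haul_id", "year", "ices_rectangle", "depth_m", "duration_min",
           "site")

  catch <- purrr::pmap(
    list(hauls$haul_id, hauls$depth_m, hauls$duration_min),
    function(hid, z, dur) {
      lambda <- dur / 60 * pool$peak_density *
        exp(-(z - pool$niche_center_m)^2 / (2 * pool$niche_breadth_m^2))
      n <- rpois(length(lambda), lambda)
      keep <- which(n > 0)
      if (length(keep) == 0) return(NULL)
      purrr::map(keep, function(i) {
        tl <- rtrunc_lnorm(n[i], pool$length_meanlog[i], pool$length_sdlog[i],
                           pool$lmax_cm[i])
        tibble(haul_id = hid, species_id = pool$species_id[i],
               length_value = tl / pool$conv_factor[i],
               length_type = pool$length_type[i])
      }) |> list_rbind()
    }) |> list_rbind()

  conv_sp <- filter(pool, .data$length_type != "TL")
  conversion_pairs <- if (nrow(conv_sp) > 0) {
    conv_sp |>
      rowwise() |>
      mutate(pairs = list({
        tl <- rtrunc_lnorm(30, .data$length_meanlog, .data$length_sdlog,
                           .data$lmax_cm)
        cf <- .data$conv_factor
        tibble(alt_length = tl / cf * exp(rnorm(30, 0, 0.02)), tl = tl)
      })) |>
      ungroup() |>
      select("species_id", "length_type", "pairs") |>
      tidyr::unnest("pairs")
  } else {
    tibble(species_id = character(), length_type = character(),
           alt_length = numeric(), tl = numeric())
  }

  lw_pairs <- pool |>
    rowwise() |>
    mutate(pairs = list({
      tl <- rtrunc_lnorm(30, .data$length_meanlog, .data$length_sdlog,
                         .data$lmax_cm)
      a <- .data$lw_a; b <- .data$lw_b
      tibble(tl_cm = tl, weight_g = a * tl^b * exp(rnorm(30, 0, 0.05)))
    })) |>
    ungroup() |>
    select("species_id", "pairs") |>
    tidyr::unnest("pairs")

  list(hauls = select(hauls, -"site"), catch = catch %||% tibble(),
       conversion_pairs = conversion_pairs, lw_pairs = lw_pairs,
       sites = sites)
}

#' Closed-form expected assemblage at a depth
#'
#' Ground truth for recovery tests: the expected catch rate of each species
#' at depth z is \eqn{\rho_s \exp(-(z - c_s)^2/(2 b_s^2))} individuals per
#' hour, and the expected individual weight uses the lognormal moment
#' \eqn{E[a L^b] = a \exp(b \mu + b^2 \sigma^2 / 2)} with the L_max
#' truncation deliberately ignored (the parameterization keeps L_max about
#' 4.8 sdlog above the median length, so the neglected mass is negligible).
#'
#' @param pool Species pool from [generate_species_pool()].
#' @param depth_m Depth of interest (m).
#' @param duration_min Haul duration used for the expected per-haul count.
#' @return A tibble: \code{species_id}, \code{expected_count} (per haul),
#'   \code{expected_count_per_h}, \code{expected_weight_g},
#'   \code{expected_cpue_kg_per_h}.
#' @export
true_assemblage <- function(pool, depth_m, duration_min = 120) {
  pool <- as_tibble(pool)
  rate <- pool$peak_density *
    exp(-(depth_m - pool$niche_center_m)^2 / (2 * pool$niche_breadth_m^2))
  ew <- pool$lw_a * exp(pool$lw_b * pool$length_meanlog +
                          pool$lw_b^2 * pool$length_sdlog^2 / 2)
  tibble(species_id = pool$species_id,
         expected_count = duration_min / 60 * rate,
         expected_count_per_h = rate,
         expected_weight_g = ew,
         expected_cpue_kg_per_h = rate * ew / 1000)
}

#' Simulate species-level stable-isotope records
#'
#' Emits individual-level isotope records whose structure encodes each
#' species' true feeding guild, for exercising [assign_guild()]: within a
#' species the isotope score increases with body length; plain
#' benthic/pelagic species straddle their class's median, high-trophic
#' species sit entirely above it, low-trophic species entirely below, and
#' suspension-associated species carry the enriched-signature flag. Species
#' labelled \code{unknown} emit no records.
#'
#' @param pool Species pool from [generate_species_pool()].
#' @param n_per_species Individuals sampled per species (default 6).
#' @param seed Integer seed.
#' @return A tibble: \code{species_id}, \code{individual_length},
#'   \code{base_class}, \code{isotope_score}, \code{suspension_flag}.
#' @export
simulate_isotope_records <- function(pool, n_per_species = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- as_tibble(pool) |> filter(.data$guild != "unknown")
  pool |>
    rowwise() |>
    mutate(rec = list({
      base <- if (startsWith(.data$guild, "benthic")) "benthic" else "pelagic"
      center <- switch(sub("^(benthic|pelagic)_?", "", .data$guild),
                       "high" = 3, "low" = -3, runif(1, -0.5, 0.5))
      len <- sort(rtrunc_lnorm(n_per_species, .data$length_meanlog,
                               .data$length_sdlog, .data$lmax_cm))
      susp <- endsWith(.data$guild, "suspension")
      tibble(individual_length = len,
             base_class = base,
             isotope_score = center +
               seq(-1.2, 1.2, length.out = n_per_species) +
               rnorm(n_per_species, 0, 0.05),
             suspension_flag = susp)
    })) |>
    ungroup() |>
    select("species_id", "rec") |>
    tidyr::unnest("rec")
}
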