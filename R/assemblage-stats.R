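#' Station-level assemblage statistics
#'
#' Effort-controlled species richness, abundance-weighted trait moments,
#' mean individual body size, isotope-rule feeding-guild assignment, and
#' guild biomass composition in 200-m depth bands.
#'
#' @name assemblage_stats
NULL

#' Effort-controlled species richness per station
#'
#' Only hauls whose duration falls inside \code{duration_window} (inclusive
#' at both ends; default 120 +/- 5 min) are counted, so richness is
#' comparable across stations. Within each qualifying haul all species are
#' counted (not just the trait-bearing subset), and the station value is the
#' mean count over its qualifying hauls. Stations with no qualifying haul
#' get a missing value.
#'
#' @param stations Stations from [pool_stations()].
#' @param hauls Haul tibble.
#' @param catch Catch tibble with \code{haul_id}, \code{species_id}.
#' @param duration_window Inclusive duration bounds in minutes.
#' @return A tibble: \code{station_id}, \code{n_qualifying_hauls},
#'   \code{richness}.
#' @export
species_richness <- function(stations, hauls, catch,
                             duration_window = c(115, 125)) {
  h <- as_tibble(hauls) |>
    filter(.data$duration_min >= duration_window[1],
           .data$duration_min <= duration_window[2])
  per_haul <- as_tibble(catch) |>
    filter(.data$haul_id %in% h$haul_id) |>
    group_by(.data$haul_id) |>
    summarise(n_species = n_distinct(.data$species_id), .groups = "drop")
  # a qualifying haul with an empty catch still counts, with zero species
  per_haul <- tibble(haul_id = h$haul_id) |>
    left_join(per_haul, by = "haul_id") |>
    mutate(n_species = coalesce(.data$n_species, 0L))
  station_members(stations) |>
    inner_join(per_haul, by = "haul_id") |>
    group_by(.data$station_id) |>
    summarise(n_qualifying_hauls = n(), richness = mean(.data$n_species),
              .groups = "drop") |>
    right_join(select(as_tibble(stations), "station_id"), by = "station_id") |>
    mutate(n_qualifying_hauls = coalesce(.data$n_qualifying_hauls, 0L))
}

#' Abundance-weighted trait means and standard deviations per station
#'
#' For each continuous trait, the station mean is the CPUE-weighted mean
#' over species with an observed value, \eqn{\bar x = \sum w_j x_j / \sum
#' w_j}, and the SD is the weighted population form \eqn{\sqrt{\sum w_j
#' (x_j - \bar x)^2 / \sum w_j}}. Species missing a trait drop out of that
#' trait's sums only.
#'
#' @param traits Species trait tibble.
#' @param cpue Station composition: \code{station_id}, \code{species_id},
#'   \code{cpue_kg_per_h}.
#' @param trait_cols Continuous trait columns (default: the canonical
#'   seven).
#' @return A long tibble: \code{station_id}, \code{trait}, \code{mean},
#'   \code{sd}, \code{n_species}.
#' @export
weighted_trait_moments <- function(traits, cpue,
                                   trait_cols = continuous_trait_columns()) {
  tr <- as_tibble(traits)
  as_tibble(cpue) |>
    filter(.data$cpue_kg_per_h > 0) |>
    inner_join(select(tr, "species_id", all_of(trait_cols)),
               by = "species_id") |>
    tidyr::pivot_longer(all_of(trait_cols), names_to = "trait",
                        values_to = "value") |>
    filter(!is.na(.data$value)) |>
    group_by(.data$station_id, .data$trait) |>
    summarise(
      mean = sum(.data$cpue_kg_per_h * .data$value) /
        sum(.data$cpue_kg_per_h),
      sd = sqrt(sum(.data$cpue_kg_per_h * (.data$value - mean)^2) /
                  sum(.data$cpue_kg_per_h)),
      n_species = n(),
      .groups = "drop")
}

#' Mean individual body length per station
#'
#' Unweighted mean total length over individuals of trait-bearing species;
#' stations with no qualifying individual get a missing value.
#'
#' @param individuals Individual register from [station_cpue()].
#' @param trait_species Character vector of trait-bearing species ids.
#' @return A tibble: \code{station_id}, \code{mean_tl_cm},
#'   \code{n_individuals}.
#' @export
mean_individual_length <- function(individuals, trait_species) {
  as_tibble(individuals) |>
    filter(.data$species_id %in% trait_species) |>
    group_by(.data$station_id) |>
    summarise(mean_tl_cm = mean(.data$tl_cm), n_individuals = n(),
              .groups = "drop")
}

#' Assign feeding guilds from stable-isotope records
#'
#' Each species is first placed in a base class (benthic or pelagic). The
#' class boundary is the median of the species-level mean isotope scores
#' within that class. A species any of whose records carries the enriched
#' suspension signature becomes \code{<base>_suspension}; otherwise, if its
#' smallest sampled individual scores strictly above the boundary it is
#' \code{<base>_high}; if its largest individual scores strictly below, it
#' is \code{<base>_low}; otherwise it keeps the plain base label (a record
#' exactly at the boundary therefore never specializes the species).
#'
#' @param records Isotope records: \code{species_id},
#'   \code{individual_length}, \code{base_class}, \code{isotope_score},
#'   \code{suspension_flag}.
#' @return A tibble: \code{species_id}, \code{guild}.
#' @export
assign_guild <- function(records) {
  r <- as_tibble(records)
  if (nrow(r) == 0) return(tibble(species_id = character(),
                                  guild = character()))
  conflicted <- r |>
    group_by(.data$species_id) |>
    summarise(k = n_distinct(.data$base_class), .groups = "drop") |>
    filter(.data$k > 1)
  if (nrow(conflicted) > 0) {
    abort(paste0("Species with conflicting base classes: ",
                 paste(conflicted$species_id, collapse = ", ")))
  }
  boundary <- r |>
    group_by(.data$base_class, .data$species_id) |>
    summarise(score = mean(.data$isotope_score), .groups = "drop_last") |>
    summarise(boundary = median(.data$score), .groups = "drop")
  r |>
    left_join(boundary, by = "base_class") |>
    group_by(.data$species_id) |>
    summarise(guild = {
      base <- first(.data$base_class)
      b <- first(.data$boundary)
      smallest <- .data$isotope_score[which.min(.data$individual_length)]
      largest <- .data$isotope_score[which.max(.data$individual_length)]
      if (any(.data$suspension_flag)) paste0(base, "_suspension")
      else if (smallest > b) paste0(base, "_high")
      else if (largest < b) paste0(base, "_low")
      else base
    }, .groups = "drop")
}

#' Guild biomass composition in depth bands
#'
#' Stations are assigned to half-open depth bands \code{[origin + k*w,
#' origin + (k+1)*w)}; within each band, trait-subset biomass (CPUE summed
#' over the band's stations) is split by feeding guild and expressed as a
#' percentage of the band total. Species without a guild label are reported
#' under \code{unknown}.
#'
#' @param cpue Station composition: \code{station_id}, \code{species_id},
#'   \code{cpue_kg_per_h} (already restricted to trait-bearing species by
#'   the caller, or restricted here via \code{trait_species}).
#' @param stations Stations tibble with \code{station_id}, \code{depth_m}.
#' @param guilds Tibble \code{species_id}, \code{guild} (e.g. from
#'   [assign_guild()] or the reference trait table).
#' @param trait_species Optional species filter.
#' @param band_width_m Band width (default 200 m).
#' @param depth_origin_m Origin of the first band (default 300 m, the
#'   survey's shallow limit).
#' @return A tibble: \code{band_lower}, \code{band_upper}, \code{guild},
#'   \code{biomass_kg_per_h}, \code{pct}.
#' @export
guild_composition <- function(cpue, stations, guilds, trait_species = NULL,
                              band_width_m = 200, depth_origin_m = 300) {
  if (band_width_m <= 0) abort("`band_width_m` must be positive.")
  comp <- as_tibble(cpue) |> filter(.data$cpue_kg_per_h > 0)
  if (!is.null(trait_species)) {
    comp <- filter(comp, .data$species_id %in% trait_species)
  }
  comp |>
    inner_join(select(as_tibble(stations), "station_id", "depth_m"),
               by = "station_id") |>
    left_join(as_tibble(guilds), by = "species_id") |>
    mutate(
      guild = coalesce(.data$guild, "unknown"),
      band_lower = depth_origin_m +
        floor((.data$depth_m - depth_origin_m) / band_width_m) * band_width_m,
      band_upper = .data$band_lower + band_width_m) |>
    group_by(.data$band_lower, .data$band_upper, .data$guild) |>
    summarise(biomass_kg_per_h = sum(.data$cpue_kg_per_h),
              .groups = "drop_last") |>
    mutate(pct = 100 * .data$biomass_kg_per_h /
             sum(.data$biomass_kg_per_h)) |>
    ungroup() |>
    arrange(.data$band_lower, .data$guild)
}
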