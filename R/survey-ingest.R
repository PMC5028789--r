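#' Survey ingest: hauls to station-level CPUE
#'
#' Reads haul/catch tables, pools hauls into depth-consistent stations
#' within ICES statistical rectangles, standardizes all measured lengths to
#' total length, predicts weights from length-weight allometry, and
#' time-averages biomass caught per hour of trawling (CPUE, kg/h) per
#' station and species — the abundance measure used by every downstream
#' statistic.
#'
#' @name survey_ingest
NULL

.length_types <- c("TL", "SL", "PAFL", "PSCFL")

#' Read haul and catch tables from delimited text
#'
#' Both files are comma-separated UTF-8 with a header row. Required columns:
#' hauls \code{haul_id, year, ices_rectangle, depth_m, duration_min}; catch
#' \code{haul_id, species_id, length_value, length_type}. Rows whose numeric
#' fields fail to parse are dropped with a message; a catch row referencing
#' an unknown haul is a fatal referential-integrity error.
#'
#' @param haul_path,catch_path Paths to the two CSV files.
#' @return A list with tibbles \code{hauls} and \code{catch}.
#' @export
read_survey_tables <- function(haul_path, catch_path) {
  for (p in c(haul_path, catch_path)) {
    if (!file.exists(p)) abort(paste0("File not found: ", p))
  }
  hauls <- readr::read_csv(haul_path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  catch <- readr::read_csv(catch_path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  need_h <- c("haul_id", "year", "ices_rectangle", "depth_m", "duration_min")
  need_c <- c("haul_id", "species_id", "length_value", "length_type")
  miss_h <- setdiff(need_h, names(hauls))
  miss_c <- setdiff(need_c, names(catch))
  if (length(miss_h) > 0) {
    abort(paste0("Haul table missing column(s): ",
                 paste(miss_h, collapse = ", ")))
  }
  if (length(miss_c) > 0) {
    abort(paste0("Catch table missing column(s): ",
                 paste(miss_c, collapse = ", ")))
  }
  hauls <- hauls |>
    mutate(year = suppressWarnings(as.integer(.data$year)),
           depth_m = suppressWarnings(as.numeric(.data$depth_m)),
           duration_min = suppressWarnings(as.numeric(.data$duration_min)))
  bad_h <- !complete.cases(hauls[c("year", "depth_m", "duration_min")]) |
    hauls$depth_m <= 0 | hauls$duration_min <= 0
  bad_h[is.na(bad_h)] <- TRUE
  if (any(bad_h)) {
    inform(sprintf("Dropped %d haul row(s) with unparseable or nonpositive values.",
                   sum(bad_h)))
    hauls <- hauls[!bad_h, ]
  }
  catch <- catch |>
    mutate(length_value = suppressWarnings(as.numeric(.data$length_value)))
  bad_c <- is.na(catch$length_value) | catch$length_value <= 0 |
    !catch$length_type %in% .length_types
  if (any(bad_c)) {
    inform(sprintf("Dropped %d catch row(s) with unparseable values or unknown length type.",
                   sum(bad_c)))
    catch <- catch[!bad_c, ]
  }
  orphans <- setdiff(catch$haul_id, hauls$haul_id)
  if (length(orphans) > 0) {
    abort(paste0("Catch rows reference unknown haul_id(s): ",
                 paste(sort(orphans), collapse = ", ")))
  }
  list(hauls = as_tibble(hauls), catch = as_tibble(catch))
}

#' Pool hauls into stations
#'
#' Within each ICES statistical rectangle, hauls are clustered by
#' complete-linkage agglomeration on depth with cutoff \code{depth_tol_m},
#' so every pair of hauls in a station differs by at most
#' \code{depth_tol_m} in depth (boundary inclusive). Singleton hauls form
#' their own stations. Station depth is the arithmetic mean of member
#' depths. The result is deterministic: hauls are ordered by depth then
#' haul id before clustering, and station ids number clusters by
#' increasing depth within each rectangle.
#'
#' @param hauls Haul tibble (see [read_survey_tables()]).
#' @param depth_tol_m Maximum pairwise depth difference within a station
#'   (default 100 m).
#' @return A tibble: \code{station_id}, \code{ices_rectangle},
#'   \code{depth_m}, \code{n_hauls}, and list-column \code{haul_ids}.
#' @export
pool_stations <- function(hauls, depth_tol_m = 100) {
  if (depth_tol_m <= 0) abort("`depth_tol_m` must be positive.")
  h <- as_tibble(hauls) |>
    arrange(.data$ices_rectangle, .data$depth_m, .data$haul_id)
  h |>
    group_by(.data$ices_rectangle) |>
    group_modify(function(df, key) {
      cl <- if (nrow(df) == 1) 1L else {
        tree <- hclust(dist(df$depth_m), method = "complete")
        cutree(tree, h = depth_tol_m)
      }
      df |>
        mutate(cluster = cl) |>
        group_by(.data$cluster) |>
        summarise(depth_m = mean(.data$depth_m), n_hauls = n(),
                  haul_ids = list(.data$haul_id), .groups = "drop") |>
        arrange(.data$depth_m) |>
        mutate(station_idx = row_number()) |>
        select(-"cluster")
    }) |>
    ungroup() |>
    mutate(station_id = sprintf("%s_S%02d", .data$ices_rectangle,
                                .data$station_idx)) |>
    select("station_id", "ices_rectangle", "depth_m", "n_hauls", "haul_ids")
}

#' Station membership as a flat table
#'
#' @param stations Output of [pool_stations()].
#' @return A tibble: \code{station_id}, \code{haul_id}.
#' @export
station_members <- function(stations) {
  as_tibble(stations) |>
    select("station_id", "haul_ids") |>
    tidyr::unnest_longer("haul_ids", values_to = "haul_id")
}

#' Estimate total-length conversion factors from paired measurements
#'
#' For each species and alternative length type, the conversion factor is
#' the arithmetic mean of the per-pair ratios TL / alternative length (mean
#' of ratios, not ratio of means or a regression slope).
#'
#' @param paired_lengths Tibble: \code{species_id}, \code{length_type},
#'   \code{alt_length}, \code{tl} (both in cm, positive).
#' @return A tibble: \code{species_id}, \code{length_type}, \code{factor},
#'   \code{n_pairs}, \code{provenance} (= "survey").
#' @export
estimate_length_conversion <- function(paired_lengths) {
  p <- as_tibble(paired_lengths)
  if (nrow(p) == 0) abort("Need at least one length pair.")
  if (any(p$alt_length <= 0) || any(p$tl <= 0)) {
    abort("Lengths must be positive.")
  }
  p |>
    group_by(.data$species_id, .data$length_type) |>
    summarise(factor = mean(.data$tl / .data$alt_length), n_pairs = n(),
              .groups = "drop") |>
    mutate(provenance = "survey")
}

# resolve one (species, type) through the factor fallback chain;
# returns NA when no level provides a factor
lookup_factor <- function(species_id, length_type, factors,
                          reference_factors, pooled_average) {
  pick <- function(tbl) {
    if (is.null(tbl)) return(NA_real_)
    hit <- tbl$factor[tbl$species_id == species_id &
                        tbl$length_type == length_type]
    if (length(hit) > 0) hit[1] else NA_real_
  }
  f <- pick(factors)
  if (is.na(f)) f <- pick(reference_factors)
  if (is.na(f)) f <- pooled_average %||% NA_real_
  f
}

#' Standardize catch lengths to total length
#'
#' TL rows pass through unchanged. Other length types are multiplied by, in
#' order of preference: a survey-derived factor, a reference (literature)
#' factor, and finally a cross-species pooled average factor. Rows that
#' exhaust the chain are dropped with a message.
#'
#' @param catch Catch tibble with \code{species_id}, \code{length_value},
#'   \code{length_type}.
#' @param factors Survey factors from [estimate_length_conversion()].
#' @param reference_factors Optional reference factor table, same columns.
#' @param pooled_average Optional single cross-species mean factor; when
#'   \code{NULL} it is computed as the mean of all supplied survey and
#'   reference factors.
#' @return The catch tibble with a new \code{tl_cm} column, unconvertible
#'   rows removed.
#' @export
standardize_total_length <- function(catch, factors = NULL,
                                     reference_factors = NULL,
                                     pooled_average = NULL) {
  ct <- as_tibble(catch)
  if (is.null(pooled_average)) {
    all_f <- c(factors$factor, reference_factors$factor)
    pooled_average <- if (length(all_f) > 0) mean(all_f) else NULL
  }
  f <- purrr::map2_dbl(ct$species_id, ct$length_type, function(sp, ty) {
    if (ty == "TL") 1 else
      lookup_factor(sp, ty, factors, reference_factors, pooled_average)
  })
  bad <- is.na(f)
  if (any(bad)) {
    inform(sprintf("Dropped %d catch row(s) with no conversion factor at any fallback level.",
                   sum(bad)))
  }
  ct |>
    mutate(tl_cm = .data$length_value * f) |>
    filter(!bad)
}

#' Fit length-weight allometry W = a * L^b
#'
#' Ordinary least squares of log weight on log length; \code{lw_a} is the
#' back-transformed intercept and \code{lw_b} the slope.
#'
#' @param paired Tibble with columns \code{tl_cm} and \code{weight_g}
#'   (positive; at least 2 distinct lengths, at least 3 pairs recommended).
#' @return A one-row tibble: \code{lw_a}, \code{lw_b}, \code{sigma_log},
#'   \code{n_pairs}.
#' @export
#' @examples
#' estimate_length_weight(data.frame(tl_cm = c(10, 20, 40),
#'                                   weight_g = 0.01 * c(10, 20, 40)^3))
estimate_length_weight <- function(paired) {
  p <- as_tibble(paired)
  if (nrow(p) < 2) abort("Need at least two length-weight pairs.")
  if (any(p$tl_cm <= 0) || any(p$weight_g <= 0)) {
    abort("Lengths and weights must be positive.")
  }
  if (length(unique(p$tl_cm)) < 2) {
    abort("Degenerate length-weight data: all lengths equal.")
  }
  fit <- lm(log(weight_g) ~ log(tl_cm), data = p)
  tibble(lw_a = exp(unname(coef(fit)[1])), lw_b = unname(coef(fit)[2]),
         sigma_log = summary(fit)$sigma, n_pairs = nrow(p))
}

#' Station-level CPUE by species, and the individual-length register
#'
#' Per haul, each individual's weight is predicted from its species'
#' length-weight parameters; species biomass per haul is divided by the
#' haul duration in hours to give CPUE (kg/h). The station value for a
#' species is the mean of its per-haul CPUE over all member hauls
#' (including hauls where the species was absent, which contribute zero) —
#' the time-averaging that removes between-year sampling variation.
#'
#' @param stations Stations from [pool_stations()].
#' @param hauls Haul tibble.
#' @param catch Catch tibble with a \code{tl_cm} column (see
#'   [standardize_total_length()]).
#' @param lw Length-weight table: \code{species_id}, \code{lw_a}, \code{lw_b}.
#' @return A list with tibbles \code{cpue} (\code{station_id},
#'   \code{species_id}, \code{cpue_kg_per_h}) and \code{individuals}
#'   (\code{station_id}, \code{haul_id}, \code{species_id}, \code{tl_cm},
#'   \code{weight_g}).
#' @export
station_cpue <- function(stations, hauls, catch, lw) {
  h <- as_tibble(hauls)
  if (any(h$duration_min <= 0)) abort("Haul durations must be positive.")
  members <- station_members(stations)
  lw <- as_tibble(lw)
  missing_lw <- setdiff(unique(catch$species_id), lw$species_id)
  if (length(missing_lw) > 0) {
    abort(paste0("No length-weight parameters for: ",
                 paste(sort(missing_lw), collapse = ", ")))
  }
  individuals <- as_tibble(catch) |>
    inner_join(members, by = "haul_id") |>
    left_join(select(lw, "species_id", "lw_a", "lw_b"), by = "species_id") |>
    mutate(weight_g = .data$lw_a * .data$tl_cm^.data$lw_b) |>
    select("station_id", "haul_id", "species_id", "tl_cm", "weight_g")

  per_haul <- individuals |>
    left_join(select(h, "haul_id", "duration_min"), by = "haul_id") |>
    group_by(.data$station_id, .data$haul_id, .data$species_id) |>
    summarise(cpue = sum(.data$weight_g) / 1000 /
                (first(.data$duration_min) / 60), .groups = "drop")

  # every species x member haul combination, absent = 0, then time-average
  n_members <- members |> count(.data$station_id, name = "n_hauls")
  cpue <- per_haul |>
    group_by(.data$station_id, .data$species_id) |>
    summarise(total = sum(.data$cpue), .groups = "drop") |>
    left_join(n_members, by = "station_id") |>
    mutate(cpue_kg_per_h = .data$total / .data$n_hauls) |>
    select("station_id", "species_id", "cpue_kg_per_h")

  # stations whose hauls caught nothing still appear, with zero total CPUE
  empty <- setdiff(stations$station_id, cpue$station_id)
  if (length(empty) > 0) {
    cpue <- bind_rows(cpue, tibble(station_id = empty,
                                   species_id = NA_character_,
                                   cpue_kg_per_h = 0))
  }
  list(cpue = arrange(cpue, .data$station_id, .data$species_id),
       individuals = individuals)
}

#' Resolve species maximum length (L_max)
#'
#' L_max is the greater of a reference (literature) maximum length —
#' converted to total length through the factor fallback chain when given
#' in another length type — and the maximum total length recorded on the
#' survey. A species with no reference length at all falls back to the
#' largest survey total length recorded for any species of the same genus.
#'
#' @param species Tibble: \code{species_id}, \code{genus}, and optional
#'   \code{ref_length}, \code{ref_type} (NA when no reference exists).
#' @param catch Catch tibble with \code{species_id} and \code{tl_cm}.
#' @param factors,reference_factors,pooled_average Conversion-factor chain
#'   as in [standardize_total_length()].
#' @return A tibble: \code{species_id}, \code{lmax_cm}, \code{lmax_source}
#'   (one of \code{reference}, \code{survey}, \code{genus}).
#' @export
resolve_lmax <- function(species, catch, factors = NULL,
                         reference_factors = NULL, pooled_average = NULL) {
  sp <- as_tibble(species)
  if (!"ref_length" %in% names(sp)) sp$ref_length <- NA_real_
  if (!"ref_type" %in% names(sp)) sp$ref_type <- NA_character_
  ct <- as_tibble(catch)
  if (is.null(pooled_average)) {
    all_f <- c(factors$factor, reference_factors$factor)
    pooled_average <- if (length(all_f) > 0) mean(all_f) else NULL
  }
  survey_max <- ct |>
    group_by(.data$species_id) |>
    summarise(survey_max_tl = max(.data$tl_cm), .groups = "drop")
  genus_max <- sp |>
    left_join(survey_max, by = "species_id") |>
    group_by(.data$genus) |>
    summarise(genus_max_tl = suppressWarnings(
      max(.data$survey_max_tl, na.rm = TRUE)), .groups = "drop") |>
    mutate(genus_max_tl = ifelse(is.finite(.data$genus_max_tl),
                                 .data$genus_max_tl, NA_real_))

  sp |>
    left_join(survey_max, by = "species_id") |>
    left_join(genus_max, by = "genus") |>
    rowwise() |>
    mutate(res = list({
      ref_tl <- if (!is.na(.data$ref_length)) {
        f <- if (.data$ref_type == "TL") 1 else
          lookup_factor(.data$species_id, .data$ref_type, factors,
                        reference_factors, pooled_average)
        if (is.na(f)) {
          abort(sprintf("No conversion factor for reference length of %s (%s).",
                        .data$species_id, .data$ref_type))
        }
        .data$ref_length * f
      } else NA_real_
      cand <- c(reference = ref_tl, survey = .data$survey_max_tl)
      if (all(is.na(cand))) {
        cand <- c(cand, genus = .data$genus_max_tl)
      }
      if (all(is.na(cand))) {
        abort(sprintf(
          "Cannot resolve L_max for %s: no reference, survey, or genus information.",
          .data$species_id))
      }
      best <- which.max(cand)
      list(lmax = unname(cand[best]), src = names(cand)[best])
    })) |>
    ungroup() |>
    mutate(lmax_cm = purrr::map_dbl(.data$res, "lmax"),
           lmax_source = purrr::map_chr(.data$res, "src")) |>
    select("species_id", "lmax_cm", "lmax_source")
}
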