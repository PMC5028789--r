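#' Pipeline orchestration
#'
#' A single entry point composing the full analysis: survey tables (synthetic
#' or user-supplied) are pooled into stations, standardized to total length,
#' converted to station CPUE, and scored with the four diversity metrics
#' (functional richness, functional divergence, similarity-sensitive size
#' diversity, effort-controlled species richness), abundance-weighted trait
#' moments, guild composition by depth band, and smooth depth trends. All
#' tabular output is comma-separated UTF-8 with headers, plus a JSON
#' manifest recording the configuration, seed, and package version.
#'
#' @name pipeline
NULL

#' Build a pipeline configuration
#'
#' @param mode \code{"synthetic"} (simulate a survey from a generated
#'   species pool) or \code{"files"} (read haul/catch CSVs).
#' @param haul_path,catch_path Input CSVs (files mode).
#' @param traits_path Optional species trait CSV; defaults to the packaged
#'   reference trait table in files mode.
#' @param lw_path Length-weight parameter CSV (\code{species_id},
#'   \code{lw_a}, \code{lw_b}; required in files mode).
#' @param factors_path Optional conversion-factor CSV (\code{species_id},
#'   \code{length_type}, \code{factor}).
#' @param seed Integer seed driving every random draw.
#' @param n_species,n_stations Synthetic scenario size (default 31 species,
#'   80 stations).
#' @param depth_tol_m Station pooling tolerance (default 100 m).
#' @param class_width_cm Size-class width (default 10 cm).
#' @param q Diversity order (default 1.1).
#' @param duration_window Richness effort window in minutes (default
#'   c(115, 125)).
#' @param band_width_m,depth_origin_m Guild band geometry (defaults 200 m
#'   from 300 m).
#' @param similarity_kernel \code{"literal"} or \code{"exponential"}.
#' @param max_axes,min_species Functional-diversity settings.
#' @param basis_dim GAM basis dimension (default 10).
#' @param out_dir Output directory.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            haul_path = NULL, catch_path = NULL,
                            traits_path = NULL, lw_path = NULL,
                            factors_path = NULL,
                            seed = 1L, n_species = 31, n_stations = 80,
                            depth_tol_m = 100, class_width_cm = 10, q = 1.1,
                            duration_window = c(115, 125),
                            band_width_m = 200, depth_origin_m = 300,
                            similarity_kernel = c("literal", "exponential"),
                            max_axes = 4, min_species = 3, basis_dim = 10,
                            out_dir = tempfile("bathytraits_run_")) {
  mode <- match.arg(mode)
  similarity_kernel <- match.arg(similarity_kernel)
  num <- c(depth_tol_m = depth_tol_m, class_width_cm = class_width_cm,
           q = q, band_width_m = band_width_m, max_axes = max_axes,
           min_species = min_species, basis_dim = basis_dim,
           n_species = n_species, n_stations = n_stations)
  if (any(num <= 0)) {
    abort(paste0("Configuration value(s) must be positive: ",
                 paste(names(num)[num <= 0], collapse = ", ")))
  }
  if (mode == "files" && (is.null(haul_path) || is.null(catch_path) ||
                          is.null(lw_path))) {
    abort("files mode requires haul_path, catch_path and lw_path.")
  }
  structure(
    list(mode = mode, haul_path = haul_path, catch_path = catch_path,
         traits_path = traits_path, lw_path = lw_path,
         factors_path = factors_path, seed = as.integer(seed),
         n_species = n_species, n_stations = n_stations,
         depth_tol_m = depth_tol_m, class_width_cm = class_width_cm, q = q,
         duration_window = duration_window, band_width_m = band_width_m,
         depth_origin_m = depth_origin_m,
         similarity_kernel = similarity_kernel, max_axes = max_axes,
         min_species = min_species, basis_dim = basis_dim,
         out_dir = out_dir),
    class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the [pipeline_config()] arguments.
#' @return A \code{pipeline_config} list.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Validate survey input files
#'
#' Schema, unit, and referential-integrity checks; failures are listed, not
#' thrown.
#'
#' @param haul_path,catch_path Input CSVs.
#' @return A tibble: \code{rule}, \code{pass}, \code{detail}.
#' @export
validate_inputs <- function(haul_path, catch_path) {
  checks <- list()
  add <- function(rule, pass, detail = "") {
    checks[[length(checks) + 1]] <<- tibble(rule = rule, pass = pass,
                                            detail = detail)
  }
  ok_files <- file.exists(haul_path) && file.exists(catch_path)
  add("files_exist", ok_files,
      if (!ok_files) "missing input file" else "")
  if (!ok_files) return(list_rbind(checks))
  hauls <- readr::read_csv(haul_path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  catch <- readr::read_csv(catch_path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  need_h <- c("haul_id", "year", "ices_rectangle", "depth_m", "duration_min")
  need_c <- c("haul_id", "species_id", "length_value", "length_type")
  miss_h <- setdiff(need_h, names(hauls))
  miss_c <- setdiff(need_c, names(catch))
  add("haul_columns", length(miss_h) == 0, paste(miss_h, collapse = ", "))
  add("catch_columns", length(miss_c) == 0, paste(miss_c, collapse = ", "))
  if (length(miss_h) > 0 || length(miss_c) > 0) return(list_rbind(checks))

  depth <- suppressWarnings(as.numeric(hauls$depth_m))
  dur <- suppressWarnings(as.numeric(hauls$duration_min))
  bad_depth <- which(is.na(depth) | depth <= 0)
  bad_dur <- which(is.na(dur) | dur <= 0)
  add("depth_positive", length(bad_depth) == 0,
      if (length(bad_depth) > 0)
        paste("rows:", paste(head(bad_depth, 5), collapse = ", ")) else "")
  add("duration_positive", length(bad_dur) == 0,
      if (length(bad_dur) > 0)
        paste("rows:", paste(head(bad_dur, 5), collapse = ", ")) else "")
  dup <- hauls$haul_id[duplicated(hauls$haul_id)]
  add("haul_id_unique", length(dup) == 0,
      paste(unique(dup), collapse = ", "))
  len <- suppressWarnings(as.numeric(catch$length_value))
  bad_len <- which(is.na(len) | len <= 0)
  add("length_positive", length(bad_len) == 0,
      if (length(bad_len) > 0)
        paste("rows:", paste(head(bad_len, 5), collapse = ", ")) else "")
  bad_type <- setdiff(unique(catch$length_type), .length_types)
  add("length_type_known", length(bad_type) == 0,
      paste(bad_type, collapse = ", "))
  orphans <- setdiff(catch$haul_id, hauls$haul_id)
  add("catch_refers_to_hauls", length(orphans) == 0,
      paste(head(sort(orphans), 5), collapse = ", "))
  list_rbind(checks)
}

#' Run the full analysis pipeline
#'
#' Executes every stage and writes the output bundle (station table,
#' per-station diversity table, trait-moment table, guild-composition table,
#' trend summaries, fitted curves, manifest) to \code{config$out_dir}.
#' Identical configuration and seed give byte-identical outputs. If any
#' stage fails, nothing is left in the output directory.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a list with all stage outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config

  if (cfg$mode == "synthetic") {
    pool <- generate_species_pool(n_species = cfg$n_species, seed = cfg$seed)
    sim <- simulate_survey(
      pool, depth_grid = seq(min(pool$niche_center_m),
                             max(pool$niche_center_m),
                             length.out = cfg$n_stations),
      seed = cfg$seed + 1L)
    hauls <- sim$hauls; catch <- sim$catch
    traits <- select(pool, "species_id", all_of(trait_columns()), "guild")
    factors <- estimate_length_conversion(sim$conversion_pairs)
    lw <- sim$lw_pairs |>
      group_by(.data$species_id) |>
      group_modify(~ estimate_length_weight(.x)) |>
      ungroup()
  } else {
    tables <- read_survey_tables(cfg$haul_path, cfg$catch_path)
    hauls <- tables$hauls; catch <- tables$catch
    traits <- if (is.null(cfg$traits_path)) load_reference_traits() else
      readr::read_csv(cfg$traits_path, show_col_types = FALSE)
    lw <- readr::read_csv(cfg$lw_path, show_col_types = FALSE)
    factors <- if (is.null(cfg$factors_path)) NULL else
      readr::read_csv(cfg$factors_path, show_col_types = FALSE)
  }
  trait_species <- traits$species_id

  stations <- pool_stations(hauls, depth_tol_m = cfg$depth_tol_m)
  catch_tl <- standardize_total_length(catch, factors)
  sc <- station_cpue(stations, hauls, catch_tl, lw)

  fd <- assemblage_fd(traits, sc$cpue, max_axes = cfg$max_axes,
                      min_species = cfg$min_species)
  spectra <- build_size_spectrum(sc$individuals, hauls, trait_species,
                                 class_width_cm = cfg$class_width_cm)
  sdiv <- station_size_diversity(spectra, q = cfg$q,
                                 kernel = cfg$similarity_kernel)
  rich <- species_richness(stations, hauls, catch,
                           duration_window = cfg$duration_window)
  moments <- weighted_trait_moments(traits, sc$cpue)
  mil <- mean_individual_length(sc$individuals, trait_species)
  guilds <- if ("guild" %in% names(traits)) {
    select(traits, "species_id", "guild")
  } else {
    tibble(species_id = trait_species, guild = "unknown")
  }
  guild_comp <- guild_composition(sc$cpue, stations, guilds,
                                  trait_species = trait_species,
                                  band_width_m = cfg$band_width_m,
                                  depth_origin_m = cfg$depth_origin_m)

  diversity <- select(as_tibble(stations), "station_id", "depth_m") |>
    left_join(select(fd, "station_id", "s_used", "fric_raw", "fric_norm",
                     "fdiv"), by = "station_id") |>
    left_join(select(sdiv, "station_id", "size_diversity"),
              by = "station_id") |>
    left_join(select(rich, "station_id", "richness"), by = "station_id") |>
    left_join(mil, by = "station_id")

  trends <- fit_depth_trends(
    diversity, metrics = c("fric_norm", "fdiv", "size_diversity", "richness"),
    basis_dim = cfg$basis_dim)
  curves <- purrr::map(trends$trend, tidy) |> list_rbind()

  out <- list(stations = stations, cpue = sc$cpue,
              individuals = sc$individuals, diversity = diversity,
              trait_moments = moments, guild_composition = guild_comp,
              trend_summaries = select(trends, -"trend"),
              trend_curves = curves, trends = trends$trend, config = cfg)
  write_pipeline_outputs(out, cfg)
  invisible(out)
}

write_pipeline_outputs <- function(out, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  tryCatch({
    w <- function(df, name) {
      path <- file.path(cfg$out_dir, name)
      readr::write_csv(df, path)
      written <<- c(written, path)
    }
    w(select(as_tibble(out$stations), -"haul_ids") |>
        mutate(haul_ids = purrr::map_chr(out$stations$haul_ids,
                                         paste, collapse = ";")),
      "stations.csv")
    w(out$cpue, "station_cpue.csv")
    w(out$diversity, "diversity.csv")
    w(out$trait_moments, "trait_moments.csv")
    w(out$guild_composition, "guild_composition.csv")
    w(out$trend_summaries, "trend_summaries.csv")
    w(out$trend_curves, "trend_curves.csv")
    manifest <- list(
      package = "bathytraits",
      version = as.character(utils::packageVersion("bathytraits")),
      seed = cfg$seed,
      config = cfg[setdiff(names(cfg), "out_dir")])
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }, error = function(e) {
    unlink(c(written, file.path(cfg$out_dir, "manifest.json")))
    abort(paste0("Failed writing pipeline outputs: ",
                 conditionMessage(e)))
  })
  invisible(cfg$out_dir)
}
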