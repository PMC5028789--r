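#' Morphometric trait engine
#'
#' Functions that turn raw morphometric measurements of individual fish into
#' the eight functional traits used throughout the package, and aggregate
#' individual values into species-level trait vectors.
#'
#' The eight traits are: relative head size (HL/TL), caudal-fin aspect ratio
#' ((TH^2/SAT)/TL), relative eye size (ED/TL), eye position (categorical),
#' mouth angle relative to the lateral line (degrees), relative surface area
#' of the mouth protrusion (SAM/TL, 0 when absent), relative gape size
#' ((pi * MH * MW / 2)/TL, in mm^2/cm), and maximum recorded length L_max (cm).
#'
#' @name trait_engine
NULL

# canonical trait column sets used across modules
.continuous_traits <- c("rel_head", "aspect_ratio", "rel_eye", "mouth_angle",
                        "rel_sam", "rel_gape", "lmax_cm")
.categorical_traits <- "eye_position"
.all_traits <- c("rel_head", "aspect_ratio", "rel_eye", "eye_position",
                 "mouth_angle", "rel_sam", "rel_gape", "lmax_cm")

#' Continuous and categorical trait column names
#'
#' Helpers returning the canonical names of the trait columns that feed the
#' functional-diversity calculations: seven continuous traits plus one
#' categorical trait (eye position).
#'
#' @return A character vector of column names.
#' @export
trait_columns <- function() .all_traits

#' @rdname trait_columns
#' @export
continuous_trait_columns <- function() .continuous_traits

#' Compute individual-level functional traits from raw measurements
#'
#' Applies the trait formulas to a table of per-individual morphometric
#' measurements. Body lengths and areas are in cm and cm^2 except mouth
#' height/width, which are measured in mm; relative gape is therefore in
#' mm^2/cm. Missing measurement values propagate to missing traits; nothing
#' is imputed. A mouth protrusion that is absent should be recorded as
#' \code{SAM = 0}, giving a true zero trait value.
#'
#' @param measurements A data frame with columns \code{species_id}, \code{TL}
#'   (total length, cm, required) and any of \code{HL}, \code{ED}, \code{TH},
#'   \code{SAT}, \code{EP}, \code{MA}, \code{SAM}, \code{MH}, \code{MW}.
#' @return A tibble with one row per individual: \code{species_id},
#'   \code{rel_head}, \code{aspect_ratio}, \code{rel_eye}, \code{eye_position},
#'   \code{mouth_angle}, \code{rel_sam}, \code{rel_gape}.
#' @export
#' @examples
#' compute_trait_vector(data.frame(species_id = "sp1", TL = 100, HL = 29))
compute_trait_vector <- function(measurements) {
  m <- as_tibble(measurements)
  if (!"TL" %in% names(m)) abort("`measurements` must contain a TL column.")
  if (any(is.na(m$TL)) || any(m$TL <= 0)) {
    abort("TL must be present and > 0 for every individual.")
  }
  opt <- function(col) if (col %in% names(m)) m[[col]] else rep(NA_real_, nrow(m))
  TL <- m$TL
  HL <- opt("HL"); ED <- opt("ED"); TH <- opt("TH"); SAT <- opt("SAT")
  MA <- opt("MA"); SAM <- opt("SAM"); MH <- opt("MH"); MW <- opt("MW")
  EP <- if ("EP" %in% names(m)) as.character(m$EP) else rep(NA_character_, nrow(m))

  bad_sat <- !is.na(TH) & !is.na(SAT) & SAT == 0
  if (any(bad_sat)) {
    warn(sprintf("%d individual(s) with SAT = 0: aspect ratio set to missing.",
                 sum(bad_sat)))
  }
  aspect <- ifelse(bad_sat, NA_real_, (TH^2 / SAT) / TL)

  tibble(
    species_id = as.character(m$species_id),
    rel_head = HL / TL,
    aspect_ratio = aspect,
    rel_eye = ED / TL,
    eye_position = EP,
    mouth_angle = MA,
    rel_sam = SAM / TL,
    # gape as the stated oval formula, mm^2 over cm
    rel_gape = (pi * MH * MW / 2) / TL
  )
}

#' Aggregate individual trait values to species level
#'
#' Continuous traits are averaged over the individuals for which they were
#' measurable; the categorical eye position takes the modal category, falling
#' back to \code{"Mixed"} when no strict majority exists. L_max and feeding
#' guild are species-level inputs joined on afterwards.
#'
#' @param individuals Output of [compute_trait_vector()] (one row per
#'   individual, with \code{species_id}).
#' @param lmax Optional tibble \code{species_id}, \code{lmax_cm}.
#' @param guild Optional tibble \code{species_id}, \code{guild}.
#' @return A tibble with one row per species holding the eight trait columns
#'   plus \code{n_measured}.
#' @export
aggregate_species_traits <- function(individuals, lmax = NULL, guild = NULL) {
  ind <- as_tibble(individuals)
  if (nrow(ind) == 0) abort("No individuals supplied.")
  cont <- intersect(.continuous_traits, names(ind))
  out <- ind |>
    group_by(.data$species_id) |>
    summarise(
      across(all_of(cont), ~ if (all(is.na(.x))) NA_real_ else
        mean(.x, na.rm = TRUE)),
      eye_position = modal_category(.data$eye_position),
      n_measured = n(),
      .groups = "drop"
    )
  if (!is.null(lmax)) out <- left_join(out, as_tibble(lmax), by = "species_id")
  if (!is.null(guild)) out <- left_join(out, as_tibble(guild), by = "species_id")
  out
}

# modal category with "Mixed" on ties; NA categories ignored
modal_category <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_character_)
  tab <- sort(table(x), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) "Mixed" else names(tab)[1]
}

# md5 of the packaged species trait table; guards against silent edits
.reference_traits_md5 <- "7e3ac891ed4c1de96fe70de175391d67"

#' Load the packaged species-level reference trait table
#'
#' Reads the packaged table of species-level traits for the 31 demersal study
#' species (seven continuous traits, eye position, feeding guild, and L_max).
#' Printed missing values (notably 13 missing caudal-fin aspect ratios) are
#' preserved as \code{NA}. The file checksum is verified on load.
#'
#' @return A tibble with 31 rows and columns \code{species_id}, \code{genus},
#'   \code{n_measured}, the eight trait columns, and \code{guild}.
#' @export
load_reference_traits <- function() {
  path <- system.file("extdata", "species_traits.csv", package = "bathytraits",
                      mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, .reference_traits_md5)) {
    abort("Packaged species trait table failed its checksum; refusing to load.")
  }
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    species_id = "c", genus = "c", eye_position = "c",
                    guild = "c", .default = "d"))
}
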