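#' Functional diversity in Gower / principal-coordinates trait space
#'
#' Functional richness (FRic) is the volume of the convex hull spanned by an
#' assemblage's species in a Euclidean trait space obtained by principal
#' coordinates analysis of the Gower dissimilarity matrix; it ignores
#' abundance. Functional divergence (FDiv) measures how biomass is
#' distributed relative to the centre of gravity of the hull vertices and is
#' bounded in [0, 1]: values near 1 mean abundance is concentrated far from
#' the centre of the occupied trait space.
#'
#' @name functional_diversity
NULL

#' Gower dissimilarity over mixed species traits
#'
#' Availability-weighted Gower coefficient: for species i, j the
#' dissimilarity is \eqn{d_{ij} = \sum_k \delta_{ijk} d_{ijk} / \sum_k
#' \delta_{ijk}}, where \eqn{\delta_{ijk} = 1} iff trait k is observed for
#' both species. Continuous traits contribute \eqn{|x_{ik} - x_{jk}|}
#' divided by the trait's range over the species pool; categorical traits
#' contribute 0 on a match and 1 otherwise. Missing traits (e.g. the 13
#' species without a measurable caudal-fin aspect ratio) simply drop out of
#' the pair's average; nothing is imputed. A continuous trait with zero
#' range over the pool contributes zero dissimilarity.
#'
#' @param traits Species trait tibble with a \code{species_id} column (e.g.
#'   from [load_reference_traits()] or [aggregate_species_traits()]).
#' @param trait_cols Trait columns to use; defaults to the canonical eight.
#' @return A symmetric dissimilarity matrix in [0, 1] with species ids as
#'   dimnames.
#' @export
gower_matrix <- function(traits, trait_cols = trait_columns()) {
  tr <- as_tibble(traits)
  missing_cols <- setdiff(trait_cols, names(tr))
  if (length(missing_cols) > 0) {
    abort(paste0("Trait column(s) not found: ",
                 paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(tr)
  if (n < 2) abort("Need at least 2 species for a dissimilarity matrix.")
  ids <- as.character(tr$species_id)
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (k in trait_cols) {
    x <- tr[[k]]
    obs <- !is.na(x)
    avail <- outer(obs, obs, `&`)
    if (is.numeric(x)) {
      rng <- diff(range(x, na.rm = TRUE))
      contrib <- if (rng > 0) abs(outer(x, x, `-`)) / rng else
        matrix(0, n, n)
    } else {
      contrib <- outer(as.character(x), as.character(x), `!=`) * 1
    }
    contrib[!avail] <- 0
    num <- num + contrib
    den <- den + avail
  }
  bare <- which(den == 0 & upper.tri(den), arr.ind = TRUE)
  if (nrow(bare) > 0) {
    abort(sprintf("Species pair with no shared observed trait: %s / %s",
                  ids[bare[1, 1]], ids[bare[1, 2]]))
  }
  d <- num / den
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  d
}

#' Principal coordinates embedding of a dissimilarity matrix
#'
#' Classical scaling: the matrix \eqn{-D^2/2} is double-centred and
#' eigendecomposed; axes with eigenvalues above \code{tol} times the largest
#' are retained (negative eigenvalues, which can arise from non-Euclidean
#' Gower matrices, are dropped without correction) and coordinates are the
#' eigenvectors scaled by the square root of their eigenvalue. For
#' reproducibility each axis is oriented so that its first nonzero loading
#' is positive.
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal (species ids
#'   as dimnames, e.g. from [gower_matrix()]).
#' @param max_axes Maximum number of axes to retain.
#' @param tol Relative eigenvalue tolerance.
#' @return A \code{trait_space} object: list with \code{species_ids},
#'   \code{coordinates} (species x axes), \code{eigenvalues}, \code{m}.
#' @export
pcoa_embed <- function(D, max_axes = nrow(D) - 1L, tol = 1e-8) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || max(abs(D - t(D))) > 1e-12 ||
      max(abs(diag(D))) > 1e-12) {
    abort("`D` must be symmetric with a zero diagonal.")
  }
  ids <- rownames(D) %||% as.character(seq_len(n))
  B <- -0.5 * D^2
  B <- sweep(B, 1, rowMeans(B))
  B <- sweep(B, 2, colMeans(B))
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  keep <- which(eig$values > tol * max(eig$values))
  if (length(keep) == 0 || max(eig$values) <= 0) {
    abort("Degenerate dissimilarity matrix: no positive-eigenvalue axis.")
  }
  keep <- keep[seq_len(min(length(keep), max_axes))]
  coords <- eig$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eig$values[keep]), length(keep))
  # orient each axis: first loading of nonnegligible magnitude is positive
  for (j in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, j]) > 1e-10)[1]
    if (!is.na(nz) && coords[nz, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- ids
  structure(
    list(species_ids = ids, coordinates = coords,
         eigenvalues = eig$values[keep], m = length(keep)),
    class = "trait_space")
}

#' @export
print.trait_space <- function(x, ...) {
  cat("<trait_space>", length(x$species_ids), "species on", x$m, "axes\n")
  cat("eigenvalues:", signif(x$eigenvalues, 4), "\n")
  invisible(x)
}

space_coords <- function(space, species = NULL, axes = NULL) {
  stopifnot(inherits(space, "trait_space"))
  species <- species %||% space$species_ids
  missing_sp <- setdiff(species, space$species_ids)
  if (length(missing_sp) > 0) {
    abort(paste0("Species not in trait space: ",
                 paste(missing_sp, collapse = ", ")))
  }
  axes <- axes %||% space$m
  space$coordinates[match(species, space$species_ids),
                    seq_len(axes), drop = FALSE]
}

#' Functional richness of a species subset
#'
#' The volume of the convex hull of the subset's coordinates on the first
#' \code{axes} axes of the trait space. Returns \code{NA} when the subset
#' has too few species (fewer than axes + 1) or is affinely degenerate.
#'
#' @param space A \code{trait_space} from [pcoa_embed()].
#' @param species Character vector of species to include (default: all).
#' @param axes Number of leading axes to use (default: all retained axes).
#' @return Hull volume (trait-space units to the power \code{axes}).
#' @export
functional_richness <- function(space, species = NULL, axes = NULL) {
  coords <- space_coords(space, species, axes)
  if (nrow(coords) <= ncol(coords)) return(NA_real_)
  h <- convex_hull(coords)
  if (h$degenerate) return(NA_real_)
  h$volume
}

#' Abundance-weighted functional divergence of a species subset
#'
#' With \eqn{g} the unweighted centroid of the hull vertices, \eqn{dG_i} the
#' distance of species i from \eqn{g}, \eqn{\bar d} the unweighted mean of
#' \eqn{dG} over the subset, and relative weights \eqn{w_i} (biomass per
#' hour, renormalized to sum to 1):
#' \deqn{\Delta d = \sum_i w_i (dG_i - \bar d), \quad
#'       \Delta|d| = \sum_i w_i |dG_i - \bar d|, \quad
#'       FDiv = (\Delta d + \bar d) / (\Delta|d| + \bar d).}
#' FDiv is invariant to rescaling all weights and lies in [0, 1].
#'
#' @inheritParams functional_richness
#' @param weights Nonnegative abundances, one per species in \code{species}
#'   order (or named by species id); at least one must be positive.
#' @return FDiv in [0, 1]; \code{NA} when the subset is degenerate or all
#'   points coincide.
#' @export
functional_divergence <- function(space, species = NULL, weights, axes = NULL) {
  species <- species %||% space$species_ids
  coords <- space_coords(space, species, axes)
  if (!is.null(names(weights))) weights <- weights[species]
  if (length(weights) != nrow(coords)) {
    abort("`weights` must have one value per species.")
  }
  if (any(is.na(weights)) || any(weights < 0) || sum(weights) <= 0) {
    abort("`weights` must be nonnegative with a positive sum.")
  }
  if (nrow(coords) <= ncol(coords)) return(NA_real_)
  h <- convex_hull(coords)
  if (h$degenerate) return(NA_real_)
  g <- colMeans(coords[h$vertices, , drop = FALSE])
  dG <- sqrt(rowSums(sweep(coords, 2, g)^2))
  dbar <- mean(dG)
  if (dbar <= 0) return(NA_real_)
  w <- weights / sum(weights)
  delta_d <- sum(w * (dG - dbar))
  delta_ad <- sum(w * abs(dG - dbar))
  (delta_d + dbar) / (delta_ad + dbar)
}

#' Station-level functional richness and divergence
#'
#' Builds one pool-level trait space (Gower dissimilarity of the supplied
#' trait table, then principal coordinates) and computes FRic and FDiv for
#' every station from its biomass-per-hour composition, restricted to the
#' trait-bearing species. The working dimensionality m is the largest value
#' not exceeding \code{max_axes} such that every included station has more
#' than m trait-bearing species; stations whose richness still falls at or
#' below m are recomputed on a reduced leading-axis subspace (their
#' normalized FRic is then relative to the pool volume in that same
#' subspace). Stations with fewer than \code{min_species} trait-bearing
#' species get missing metrics.
#'
#' @param traits Species trait tibble (pool definition).
#' @param cpue Station composition tibble: \code{station_id},
#'   \code{species_id}, \code{cpue_kg_per_h}.
#' @param max_axes Upper bound on embedding axes (default 4).
#' @param min_species Minimum trait-bearing species for a station to be
#'   scored (default 3).
#' @param normalize Report FRic relative to the pool hull volume
#'   (\code{fric_norm}) alongside the raw volume.
#' @return A tibble: \code{station_id}, \code{s_used}, \code{m_used},
#'   \code{fric_raw}, \code{fric_norm}, \code{fdiv}.
#' @export
assemblage_fd <- function(traits, cpue, max_axes = 4, min_species = 3,
                          normalize = TRUE) {
  tr <- as_tibble(traits)
  comp <- as_tibble(cpue) |>
    filter(.data$species_id %in% tr$species_id, .data$cpue_kg_per_h > 0)
  D <- gower_matrix(tr)
  space <- pcoa_embed(D, max_axes = max_axes)

  stations <- comp |>
    group_by(.data$station_id) |>
    summarise(s_used = n_distinct(.data$species_id), .groups = "drop")
  usable <- stations$s_used[stations$s_used >= min_species]
  if (length(usable) == 0) {
    abort("No station has enough trait-bearing species.")
  }
  m <- min(space$m, max_axes, min(usable) - 1L)
  m <- max(m, 1L)
  pool_vol <- vapply(seq_len(m), function(a)
    functional_richness(space, axes = a), numeric(1))

  dropped <- sum(stations$s_used < min_species)
  if (dropped > 0) {
    inform(sprintf(
      "%d station(s) with fewer than %d trait-bearing species: metrics missing.",
      dropped, min_species))
  }

  res <- comp |>
    group_by(.data$station_id) |>
    group_modify(function(df, key) {
      sp <- df$species_id
      w <- setNames(df$cpue_kg_per_h, sp)
      s <- length(sp)
      if (s < min_species) {
        return(tibble(s_used = s, m_used = NA_integer_, fric_raw = NA_real_,
                      fric_norm = NA_real_, fdiv = NA_real_))
      }
      m_s <- min(m, s - 1L)
      fric <- functional_richness(space, sp, axes = m_s)
      fdiv <- functional_divergence(space, sp, weights = w, axes = m_s)
      tibble(s_used = s, m_used = as.integer(m_s), fric_raw = fric,
             fric_norm = if (normalize) fric / pool_vol[m_s] else NA_real_,
             fdiv = fdiv)
    }) |>
    ungroup()
  res
}
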