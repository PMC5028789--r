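# shared fixtures and oracles, all built in code

# tiny haul/catch tables written to temp CSVs
write_survey_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  hauls <- data.frame(
    haul_id = c("H1", "H2"),
    year = c(2000L, 2001L),
    ices_rectangle = c("R1", "R1"),
    depth_m = c(400, 450),
    duration_min = c(120, 118))
  catch <- data.frame(
    haul_id = c("H1", "H1", "H2"),
    species_id = c("spA", "spB", "spA"),
    length_value = c(30, 50, 35),
    length_type = c("TL", "SL", "TL"))
  hp <- file.path(dir, "hauls.csv"); cp <- file.path(dir, "catch.csv")
  utils::write.csv(hauls, hp, row.names = FALSE)
  utils::write.csv(catch, cp, row.names = FALSE)
  list(haul_path = hp, catch_path = cp, hauls = hauls, catch = catch)
}

# a small species trait table with clean geometry for hand-computable cases
toy_traits <- function() {
  tibble::tibble(
    species_id = c("s1", "s2", "s3", "s4"),
    rel_head = c(0.1, 0.3, 0.1, 0.3),
    aspect_ratio = c(1, 1, 5, 5),
    rel_eye = c(0.01, 0.11, 0.01, 0.11),
    eye_position = c("Side", "Side", "Top", "Top"),
    mouth_angle = c(10, 50, 10, 50),
    rel_sam = c(0, 1, 0, 1),
    rel_gape = c(5, 100, 5, 100),
    lmax_cm = c(30, 150, 30, 150))
}

# independent rejection-sampling volume oracle (python/numpy/scipy):
# uniform draws in the bounding box, membership via Delaunay triangulation
rejection_volume <- function(points, n_samples = 1e6, seed = 0) {
  dir <- withr::local_tempdir()
  pfile <- file.path(dir, "pts.csv")
  ofile <- file.path(dir, "out.txt")
  utils::write.table(points, pfile, row.names = FALSE, col.names = FALSE,
                     sep = ",")
  script <- sprintf('
import numpy as np
from scipy.spatial import Delaunay
rng = np.random.default_rng(%d)
p = np.loadtxt("%s", delimiter=",", ndmin=2)
tri = Delaunay(p)
lo, hi = p.min(axis=0), p.max(axis=0)
x = rng.uniform(lo, hi, size=(%d, p.shape[1]))
inside = tri.find_simplex(x) >= 0
box = np.prod(hi - lo)
print(float(inside.mean() * box))
', seed, pfile, as.integer(n_samples))
  sfile <- file.path(dir, "vol.py")
  writeLines(script, sfile)
  out <- system2("python", sfile, stdout = TRUE)
  as.numeric(out[length(out)])
}

# deterministic Euclidean point cloud for PCoA round-trips
euclid_config <- function(n = 8, d = 3, seed = 5) {
  set.seed(seed)
  matrix(stats::rnorm(n * d), n, d)
}
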