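# fixture builders: everything is generated in code at test time

identity_dir <- cbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))

make_volume <- function(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  image_volume(arr, origin, spacing, identity_dir,
               modality = "CT", patient_id = "T-001")
}

make_mask <- function(bits, vol, name = "roi") {
  binary_mask(bits, name, vol$origin, vol$spacing, vol$direction)
}

# a region with prescribed raw values along a line (1 x 1 x n grid)
line_region <- function(values, bin_width = 25) {
  arr <- array(as.numeric(values), dim = c(1, 1, length(values)))
  vol <- make_volume(arr)
  m <- make_mask(array(TRUE, dim(arr)), vol)
  discretize_fbw(vol, m, bin_width)
}

# region from an explicit integer level array (treated as both raw and level)
level_region <- function(levels_arr) {
  arr <- array(as.numeric(levels_arr), dim = dim(levels_arr))
  vol <- make_volume(arr)
  m <- make_mask(!is.na(levels_arr), vol)
  discretize_fbw(vol, m, 1)
}

# digitized sphere mask: radius mm on an isotropic grid
sphere_mask <- function(radius = 20, spacing = 1, margin = 3) {
  n <- 2L * ceiling(radius / spacing) + 2L * margin + 1L
  ctr <- (n - 1) / 2
  k <- slice.index(array(0L, c(n, n, n)), 1) - 1L
  r <- slice.index(array(0L, c(n, n, n)), 2) - 1L
  cc <- slice.index(array(0L, c(n, n, n)), 3) - 1L
  bits <- ((k - ctr)^2 + (r - ctr)^2 + (cc - ctr)^2) * spacing^2 <= radius^2
  vol <- make_volume(array(0, c(n, n, n)), spacing = rep(spacing, 3))
  make_mask(bits, vol, "sphere")
}

# standard sphere-lesion DICOM phantom case used across tests
sphere_case <- function(dir, patient_id = "PH-001", seed = 20190101L) {
  spec <- phantom_spec(
    grid_shape = c(16L, 32L, 32L), spacing = c(2, 1, 1),
    intensity = intensity_sphere_lesion(center = c(16, 16, 15), radius = 10,
                                        fg = 100L, bg = -50L),
    rois = list(roi_spec("GTV-1", shape_circle(c(16, 16), 12, 64), 3:12)),
    patient_id = patient_id, seed = seed)
  make_case(spec, dir)
}

# random ROI generator for rasterization agreement runs; geometry avoids
# voxel-center-grazing contours (edges sit strictly between centers)
random_roi_spec <- function(rng_case, nr = 20L, nc = 20L) {
  kind <- sample(c("rectangle", "circle", "ring"), 1L)
  if (kind == "rectangle") {
    a <- sample(2:(nc - 10), 1); b <- a + sample(3:6, 1)
    d <- sample(2:(nr - 10), 1); e <- d + sample(3:6, 1)
    sh <- shape_rectangle(center = c((a + b) / 2, (d + e) / 2),
                          extents = c(b - a, e - d))
  } else if (kind == "circle") {
    sh <- shape_circle(center = c(nc / 2 + runif(1, -2, 2) + 0.3,
                                  nr / 2 + runif(1, -2, 2) + 0.3),
                       radius = runif(1, 3, min(nr, nc) / 2 - 3), 64L)
  } else {
    ctr <- c(nc / 2 + 0.3, nr / 2 + 0.3)
    r_out <- runif(1, 5, min(nr, nc) / 2 - 3)
    sh <- shape_ring(shape_circle(ctr, r_out, 64L),
                     shape_circle(ctr, runif(1, 2, r_out - 2), 32L))
  }
  roi_spec(paste0("roi-", kind), sh, sample(0:2, sample(1:2, 1)))
}
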