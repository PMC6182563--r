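# masks and single-object scenes used across the test files

# logical disk mask: pixel centers within radius r, with `pad` background
mask_disk <- function(r, pad = 6) {
  n <- 2 * r + 2 * pad + 1
  c0 <- pad + r + 1
  xy <- expand.grid(y = seq_len(n), x = seq_len(n))
  matrix((xy$x - c0)^2 + (xy$y - c0)^2 <= r^2, n, n)
}

mask_rect <- function(w, h, pad = 4) {
  m <- matrix(FALSE, h + 2 * pad, w + 2 * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- TRUE
  m
}

# disk of radius r with `n_spikes` radial spikes of the given length (1 px wide)
mask_spiky_disk <- function(r, n_spikes, spike_len, pad = 6) {
  size <- 2 * (r + spike_len) + 2 * pad + 1
  c0 <- (size + 1) / 2
  xy <- expand.grid(y = seq_len(size), x = seq_len(size))
  m <- matrix((xy$x - c0)^2 + (xy$y - c0)^2 <= r^2, size, size)
  for (k in seq_len(n_spikes)) {
    ang <- 2 * pi * (k - 1) / n_spikes
    tt <- seq(0, r + spike_len, by = 0.5)
    px <- round(c0 + tt * cos(ang)); py <- round(c0 + tt * sin(ang))
    ok <- px >= 1 & px <= size & py >= 1 & py <= size
    m[cbind(py[ok], px[ok])] <- TRUE
  }
  m
}

# a scene holding exactly the given full-frame masks as truth objects
scene_from_masks <- function(masks, calibration = 1, seed = 1, ...) {
  h <- nrow(masks[[1]]); w <- ncol(masks[[1]])
  sc <- scene_new(width = w, height = h, calibration = calibration,
                  seed = seed, ...)
  for (m in masks) {
    sc <- mycomorph:::scene_add_object(sc, which(m), kind = "spore",
                                       cx = mean(which(m, arr.ind = TRUE)[, 2]),
                                       cy = mean(which(m, arr.ind = TRUE)[, 1]),
                                       reach = 1)
  }
  sc
}

# render a mask list and run the full pipeline without filters
measure_rendered <- function(masks, calibration = 1, config = default_config()) {
  sc <- scene_from_masks(masks, calibration = calibration)
  analyze_image(render_scene(sc), config = config, image_kind = "none")
}

# random small blob: a few stamped disks, always 8-connected
random_blob_mask <- function(seed, size = 40) {
  set.seed(seed)
  m <- matrix(FALSE, size, size)
  cx <- size / 2; cy <- size / 2
  for (k in 1:4) {
    r <- runif(1, 2, 5)
    dx <- runif(1, -5, 5); dy <- runif(1, -5, 5)
    xy <- expand.grid(y = seq_len(size), x = seq_len(size))
    m <- m | matrix((xy$x - cx - dx)^2 + (xy$y - cy - dy)^2 <= r^2, size, size)
  }
  m
}
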