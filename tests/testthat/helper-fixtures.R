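# Small construction helpers shared across test files.

vol3 <- function(a, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  image_volume(array(as.numeric(a), dim(a)), spacing, origin)
}

mask3 <- function(a, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  roi_mask(array(a, dim(a)), spacing, origin)
}

# volume/mask pair from a vector of in-mask values laid out in a grid of
# the same size (mask = everything)
full_pair <- function(values_array, spacing = c(1, 1, 1)) {
  list(volume = vol3(values_array, spacing),
       mask = mask3(array(TRUE, dim(values_array)), spacing))
}

# digital ball of radius r (voxel units) at unit spacing
ball_mask <- function(r, spacing = c(1, 1, 1)) {
  n <- 2 * ceiling(r) + 3
  ctr <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  inside <- ((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2) <= r^2
  mask3(array(inside, c(n, n, n)), spacing)
}

# quick survival frame from vectors
surv_df <- function(time, event, ...) {
  data.frame(time_months = time, event = event, ...)
}
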