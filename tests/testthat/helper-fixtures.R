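# Shared fixtures, built in code at test time.

# small geometric volume_grid with a given constant or generator
make_grid <- function(shape = c(8L, 8L, 8L), spacing = c(1, 1, 1),
                      origin = c(0, 0, 0), units = "HU",
                      fill = function(n) rnorm(n)) {
  vals <- if (is.function(fill)) array(fill(prod(shape)), dim = shape)
          else array(fill, dim = shape)
  volume_grid(vals, spacing_mm = spacing, origin_mm = origin, units = units)
}

# analytic ellipsoid mask on a grid centered at `center` (world mm)
ellipsoid_grid <- function(shape, spacing, center, semi, origin = NULL) {
  origin <- origin %||% (-(shape - 1) / 2 * spacing)
  co <- lapply(1:3, function(a) origin[a] + (seq_len(shape[a]) - 1) * spacing[a])
  vals <- array(0, dim = shape)
  for (z in seq_len(shape[3]))
    for (y in seq_len(shape[2]))
      vals[, y, z] <- as.numeric(((co[[1]] - center[1]) / semi[1])^2 +
                                 ((co[[2]][y] - center[2]) / semi[2])^2 +
                                 ((co[[3]][z] - center[3]) / semi[3])^2 <= 1)
  volume_grid(vals, spacing_mm = spacing, origin_mm = origin, units = "binary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cached desk-scale phantom (expensive pieces reused across tests)
cached_phantom <- local({
  ph <- NULL
  function(seed = 11L, index = 1L) {
    if (is.null(ph)) ph <<- generate_phantom(phantom_config_test(seed = seed), index)
    ph
  }
})

# brute-force Dice by explicit voxel-set intersection (independent oracle)
dice_bruteforce <- function(a, b) {
  ia <- which(a != 0)
  ib <- which(b != 0)
  if (length(ia) + length(ib) == 0) return(1)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}
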