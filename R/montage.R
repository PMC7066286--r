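#' Standard 32-channel 10-10 montage
#'
#' Approximate spherical positions (unit head sphere) for the 32-channel
#' extended 10-20 ("10-10") cap used throughout the package. Angles follow the
#' usual convention: inclination is the polar angle from the vertex (Cz = 0
#' degrees) and azimuth is measured from the nasion, positive towards the
#' right ear, so the back of the head is at +/-180 degrees.
#'
#' Positions are only used to shape smooth spatial profiles (parietal P300
#' topography, frontal blink gradient); they are not a forward model.
#'
#' @return A tibble with columns `channel`, `inclination_deg`, `azimuth_deg`,
#'   `x`, `y`, `z` (unit sphere; x towards nasion, y towards right ear,
#'   z towards vertex).
#' @export
#' @examples
#' montage_1010()
montage_1010 <- function() {
  m <- tibble::tribble(
    ~channel, ~inclination_deg, ~azimuth_deg,
    "Fp1",  72,  -18,
    "Fp2",  72,   18,
    "F7",   72,  -54,
    "F3",   50,  -29,
    "Fz",   36,    0,
    "F4",   50,   29,
    "F8",   72,   54,
    "FT9",  90,  -72,
    "FC5",  60,  -62,
    "FC1",  29,  -40,
    "FC2",  29,   40,
    "FC6",  60,   62,
    "FT10", 90,   72,
    "T7",   72,  -90,
    "C3",   36,  -90,
    "Cz",    0,    0,
    "C4",   36,   90,
    "T8",   72,   90,
    "TP9",  90, -108,
    "CP5",  60, -118,
    "CP1",  29, -140,
    "CP2",  29,  140,
    "CP6",  60,  118,
    "TP10", 90,  108,
    "P7",   72, -126,
    "P3",   50, -151,
    "Pz",   36,  180,
    "P4",   50,  151,
    "P8",   72,  126,
    "O1",   72, -162,
    "Oz",   72,  180,
    "O2",   72,  162
  )
  inc <- m$inclination_deg * pi / 180
  az <- m$azimuth_deg * pi / 180
  m$x <- sin(inc) * cos(az)
  m$y <- sin(inc) * sin(az)
  m$z <- cos(inc)
  m
}

# internal: cosine-falloff weights relative to a reference electrode.
# weight = max(cos(great-circle angle), 0), so the reference channel gets 1
# and channels more than 90 degrees away get 0.
spatial_profile <- function(channels, reference, floor = 0) {
  m <- montage_1010()
  pos <- m[match(channels, m$channel), c("x", "y", "z")]
  if (anyNA(pos$x)) {
    missing <- channels[is.na(pos$x)]
    abort(sprintf("Unknown 10-10 channel label(s): %s",
                  paste(missing, collapse = ", ")),
          class = "oddlock_parameter_error")
  }
  ref <- m[match(reference, m$channel), c("x", "y", "z")]
  if (anyNA(ref$x)) {
    abort(sprintf("Unknown reference channel `%s`.", reference),
          class = "oddlock_parameter_error")
  }
  cosang <- as.numeric(as.matrix(pos) %*% t(as.matrix(ref)))
  w <- pmax(cosang, 0)
  floor + (1 - floor) * w
}

# internal: default channel subset of a given size, always containing Pz and
# the frontal channels used for blink modelling / EOG proxying.
default_channels <- function(n) {
  all <- montage_1010()$channel
  core <- c("Pz", "Fp1", "Fp2", "Fz", "Cz", "P3", "P4", "CP1", "CP2", "Oz",
            "C3", "C4", "F3", "F4", "P7", "P8")
  sel <- unique(c(core, all))[seq_len(n)]
  all[all %in% sel]   # keep montage order
}
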