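# Shared fixtures: a scaled-down rig (same field of view as the full
# 1280x720 / 384x288 rig) and memoized synthetic scenes so expensive
# renders are reused across tests within a run.

test_rig <- function(scale = 0.25, ...) make_rig(image_scale = scale, ...)

.scene_cache <- new.env(parent = emptyenv())

cached_scene <- function(seed = 3, ...) {
  key <- paste0("s", seed, "_", paste(deparse(list(...)), collapse = ""))
  key <- substr(gsub("[^a-z0-9]", "", tolower(key)), 1, 80)
  if (is.null(.scene_cache[[key]])) {
    .scene_cache[[key]] <- render_canopy_scene(test_rig(), seed = seed, ...)
  }
  .scene_cache[[key]]
}

# small deterministic textured grayscale image for feature tests
textured_image <- function(h = 120, w = 160, seed = 5) {
  set.seed(seed)
  base <- matrix(runif(ceiling(h / 8) * ceiling(w / 8)), ceiling(h / 8))
  big <- base[rep(seq_len(nrow(base)), each = 8)[1:h],
              rep(seq_len(ncol(base)), each = 8)[1:w]]
  g <- canopy3d:::gaussian_blur(big * 255, 1.2)
  g + matrix(runif(h * w, 0, 12), h, w)
}
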