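# Fixtures built in code: ideal wedge profiles and small cached scenes.

# Two straight segments meeting at the given interior angle in
# (height, depth) world mm, ankle-deepest orientation (both arms rise
# toward the camera relative to the vertex). Returns an unrotated
# world-space profile plus the vertex index.
make_wedge <- function(angle_deg, n_foot = 20, n_leg = 25,
                       foot_len = 150, leg_len = 300, g_deg = -30,
                       ankle = c(0, 2000)) {
  a2 <- (g_deg) * pi / 180          # leg direction, away from the vertex
  a1 <- (g_deg - angle_deg) * pi / 180  # foot direction, away from the vertex
  tf <- seq(foot_len, foot_len / n_foot, length.out = n_foot)
  tl <- seq(leg_len / n_leg, leg_len, length.out = n_leg)
  h <- c(ankle[1] + tf * cos(a1), ankle[1], ankle[1] + tl * cos(a2))
  d <- c(ankle[2] + tf * sin(a1), ankle[2], ankle[2] + tl * sin(a2))
  list(profile = ankleproj:::world_profile(h, d),
       ankle_index = as.integer(n_foot) + 1L)
}

# Scenes are slow to render; cache them per test run.
.scene_cache <- new.env(parent = emptyenv())
cached_scene <- function(key, spec) {
  if (is.null(.scene_cache[[key]]))
    .scene_cache[[key]] <- render_scene(spec)
  .scene_cache[[key]]
}

demo_scene <- function() {
  cached_scene("demo", scene_spec(distance_mm = 2000, ankle_angle_deg = 90,
                                  duration_s = 0.2, seed = 11))
}
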