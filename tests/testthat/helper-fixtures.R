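# Shared fixtures: a small dish scene so image tests stay fast, and the
# water surface area of the 145-mm crystallizing dish.

WATER_AREA_145MM <- pi * 0.0725^2  # m^2, from the 145-mm inner diameter

small_scene <- function(seed = 1L, ...) {
  scene_spec(image_width_px = 200L, image_height_px = 200L,
             dish_center_px = c(100, 100), dish_radius_px = 90,
             metres_per_px = 0.0725 / 90, seed = seed, ...)
}

small_geometry <- function(scene = small_scene()) {
  list(center_px = scene$dish_center_px, radius_px = scene$dish_radius_px,
       metres_per_px = scene$metres_per_px)
}

# brute-force check that a compact letter display encodes exactly the
# pairwise decisions: every pair shares a letter iff not significant
letters_match_decisions <- function(letters, pairwise) {
  for (r in seq_len(nrow(pairwise))) {
    li <- strsplit(letters[[pairwise$group_i[r]]], "")[[1]]
    lj <- strsplit(letters[[pairwise$group_j[r]]], "")[[1]]
    shared <- length(intersect(li, lj)) > 0
    if (shared == pairwise$significant[r]) return(FALSE)
  }
  TRUE
}
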