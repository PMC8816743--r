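# Shared fixtures: compact scene configurations (smaller canvas than the
# defaults, same physics) and the per-cell analysis pipeline used by several
# test files.

quick_cfg <- function(...) {
  scene_config(image_size_px = 288, soma_radius_um = 6, axon_length_um = 50,
               ...)
}

movie_cfg <- function(seed, cluster_present = TRUE, ...) {
  scene_config(image_size_px = c(96, 400), n_dendrites = 0,
               cluster_present = cluster_present, seed = seed, ...)
}

# scene -> AIS start, mito mask, presence + intensity profiles, cluster call
analyze_cell <- function(scene, criteria = cluster_criteria()) {
  path <- scene$annotations$paths[[1]]
  start <- detect_ais_start(extract_profile(scene$stack, "AIS", path))
  mask <- segment_mitochondria(scene$stack)
  presence <- binary_presence_profile(mask, path,
                                      scene$stack$pixel_size_um)
  intensity <- extract_profile(scene$stack, "MITO", path)
  call <- classify_cluster(presence, intensity, start, criteria)
  list(start = start, mask = mask, presence = presence,
       intensity = intensity, call = call)
}

# straight horizontal path across a [Y, X] image, at row y_px
straight_path <- function(cell_id, x0, x1, y_px, role = "axon") {
  path_annotation(cell_id, role, cbind(c(x0, x1), c(y_px, y_px)))
}

# single-channel stack from a matrix
matrix_stack <- function(m, pixel_size_um = 0.25, channel = "ch") {
  image_stack(m, channel, pixel_size_um)
}
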