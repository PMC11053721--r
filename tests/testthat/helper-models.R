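# Shared fixtures: reference models and schema are deterministic and cheap
# to build, but caching them keeps the suite fast.
.fixtures <- new.env(parent = emptyenv())

ref_mesh <- function(jaw) {
  key <- paste0("mesh_", jaw)
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build_model(default_spec(jaw))
  .fixtures[[key]]
}

ref_schema <- function() {
  if (is.null(.fixtures$schema)) .fixtures$schema <- enumerate_feature_sizes()
  .fixtures$schema
}

# Signed volume of a triangle mesh (positive for outward-oriented solids).
mesh_volume <- function(m) {
  a <- m$vertices[m$faces[, 1], , drop = FALSE]
  b <- m$vertices[m$faces[, 2], , drop = FALSE]
  c_ <- m$vertices[m$faces[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# Region -> label lookup for a labeled mesh.
face_labels <- function(mesh) {
  lab <- rep(NA_character_, nrow(mesh$faces))
  for (rn in names(mesh$regions)) lab[mesh$regions[[rn]]] <- rn
  lab
}

expect_same_regions <- function(a, b) {
  expect_setequal(names(a$regions), names(b$regions))
  for (rn in names(a$regions))
    expect_true(setequal(a$regions[[rn]], b$regions[[rn]]),
                label = sprintf("region '%s' face set preserved", rn))
}
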