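# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# Small rendered cohort for I/O, pipeline, and property tests.
small_cohort <- function(n = 10, seed = 101) {
  key <- sprintf("cohort_%d_%d", n, seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generateCohort(n, seed)
  .fixture_cache[[key]]
}

# Landmark templates only (no rendering) -- cheap, for geometry statistics.
template_set <- function(n = 98, seed = 101, view = "frontal") {
  key <- sprintf("tpl_%s_%d_%d", view, n, seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- lapply(seq_len(n), function(i)
      landmarkTemplate(sampleSubject(i, seed), view))
  .fixture_cache[[key]]
}

# A minimal valid AnnotatedImage with given landmarks (tiny pixel array).
tiny_image <- function(landmarks, view = "frontal", subject = "T001",
                       width = 100L, height = 120L) {
  annotatedImage(subject, view, array(128, dim = c(height, width, 3)),
                 landmarks)
}

# Schema-complete landmark frame placed on a grid inside a width x height
# image.
grid_landmarks <- function(view = "frontal", width = 100, height = 120) {
  nms <- landmarkNames(landmarkSchema(view))
  n <- length(nms)
  data.frame(name = nms,
             x = seq(5, width - 6, length.out = n),
             y = seq(5, height - 6, length.out = n))
}
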