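# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small corresponded training population + shape model (fast, reused widely)
test_model <- function() {
  fixture("model", function() {
    pop <- sample_population(25, seed = 42)
    build_shape_model(pop)
  })
}

test_population <- function() {
  fixture("population", function() sample_population(25, seed = 42))
}

# the spec-sized phantom: block 80 x 80 x 60 mm, cup radius 25 mm
test_phantom <- function() {
  fixture("phantom", function() {
    make_phantom(phantom_params(block_half_extents = c(40, 40, 30),
                                cup_radius = 25), seed = 1)
  })
}

# dense-sampling oracle for ray classification: membership of sampled stations
# in (inside native) AND (NOT inside pathological), from the hit lists alone
interval_oracle <- function(native_hits, patho_hits, max_range, ts) {
  inside <- function(hits, t) {
    h <- hits
    if (length(h) %% 2L == 1L) h <- c(h, max_range)
    if (length(h) == 0L) return(rep(FALSE, length(t)))
    iv <- matrix(h, ncol = 2, byrow = TRUE)
    out <- rep(FALSE, length(t))
    for (k in seq_len(nrow(iv))) out <- out | (t > iv[k, 1] & t < iv[k, 2])
    out
  }
  inside(native_hits, ts) & !inside(patho_hits, ts) & ts > 0 & ts < max_range
}

# membership of sampled stations according to classify_ray's intervals
interval_membership <- function(intervals, ts) {
  out <- rep(FALSE, length(ts))
  if (nrow(intervals) == 0L) return(out)
  for (k in seq_len(nrow(intervals)))
    out <- out | (ts > intervals[k, 1] & ts < intervals[k, 2])
  out
}
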