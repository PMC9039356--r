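# Session-cached fixtures shared across test files (built once, in code).

.fixture_cache <- new.env(parent = emptyenv())

cached_walk <- function(seed = 7) {
  key <- paste0("walk", seed)
  if (!exists(key, envir = .fixture_cache)) {
    fx <- make_walk_fixture(seed = seed)
    perm <- setNames(fx$wwps$sequence, fx$wwps$name)
    res <- simulate_walk(fx$genome, fx$known_region, fx$gsps, perm)
    assign(key, list(fx = fx, res = res), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}
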