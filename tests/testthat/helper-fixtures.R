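# shared fixtures, built in code

checkerboard <- function(n = 8, lo = 0, hi = 255) {
  outer(seq_len(n), seq_len(n), function(i, j) ifelse((i + j) %% 2 == 0, hi, lo))
}

# a dark square on white background
discImage <- function(size = 16, lo = 40) {
  m <- matrix(255, size, size)
  q <- floor(size / 3)
  m[(q + 1):(2 * q), (q + 1):(2 * q)] <- lo
  m
}

# linearly separable two-class image set (dark vs bright)
separableImages <- function(nPerClass = 30, size = 32, seed = 1) {
  set.seed(seed)
  imgs <- c(replicate(nPerClass, matrix(runif(size^2, 0, 80), size, size),
                      simplify = FALSE),
            replicate(nPerClass, matrix(runif(size^2, 150, 255), size, size),
                      simplify = FALSE))
  list(images = imgs, labels = rep(1:2, each = nPerClass))
}

# independent brute-force SMD2: explicit double loop over valid pixels
smd2BruteForce <- function(m) {
  acc <- 0
  for (y in seq_len(nrow(m) - 1))
    for (x in seq_len(ncol(m) - 1))
      acc <- acc + abs(m[y, x] - m[y, x + 1]) * abs(m[y, x] - m[y + 1, x])
  acc
}

# independent macro-precision: per-item counting from prediction lists
macroPBruteForce <- function(trueLabels, predLabels, nClasses) {
  ps <- numeric(nClasses)
  for (cl in seq_len(nClasses)) {
    predicted <- which(predLabels == cl)
    ps[cl] <- if (length(predicted) == 0) 0
              else sum(trueLabels[predicted] == cl) / length(predicted)
  }
  mean(ps)
}

# independent downsampling-round count: smallest N whole rounds of k*cMin
# removals that could cover ci (enumeration, not the closed form)
downsampleRoundsBruteForce <- function(ci, cMin, k) {
  N <- 1
  while (N * k * cMin < ci - 1e-9) N <- N + 1
  N
}
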