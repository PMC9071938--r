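# Shared fixtures, built in code at test time.

# random complex matrix with a fixed seed
randomComplex <- function(n, seed = 1) {
  set.seed(seed)
  matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
}

# smooth non-negative magnitude (bandlimited, safely positive everywhere)
smoothMagnitude <- function(n = 64) {
  x <- seq(-1, 1, length.out = n)
  0.5 + 0.4 * outer(exp(-x^2 / 0.3), exp(-x^2 / 0.5))
}

# one undersampled 2D sample (kMeas, mask, target) from a phantom slice
sliceSample <- function(subject, z, accel = 4, seed = 1) {
  sl <- subject@complexImage@values[, , z]
  mask <- makeSamplingMask(dim(sl), accel, 0.08, seed = seed)
  km <- imgValues(forwardFFT(complexImage(sl)))
  km[!maskKeep(mask)] <- 0 + 0i
  list(kMeas = km, mask = mask, target = sl)
}

# build train/test slice sets from phantom subjects
makeSliceSets <- function(nTrainSubj = 4, nTestSubj = 2, slicesPer = 8,
                          seed = 100) {
  subjects <- lapply(seq_len(nTrainSubj + nTestSubj), function(i)
    makePhantom(randomPhantomSpec(seed = seed + i),
                subjectId = sprintf("S%d", i)))
  mk <- function(ids, base) {
    out <- list()
    for (i in ids) {
      v <- subjects[[i]]@complexImage@values
      zmid <- dim(v)[3] %/% 2
      zr <- (zmid - slicesPer %/% 2 + 1):(zmid + slicesPer %/% 2)
      for (z in zr)
        out[[length(out) + 1]] <- sliceSample(subjects[[i]], z,
                                              seed = base + i * 100 + z)
    }
    out
  }
  list(train = mk(seq_len(nTrainSubj), 0),
       test = mk(nTrainSubj + seq_len(nTestSubj), 9999))
}

# give every parameter of a model small random values (seeded)
randomizeModel <- function(model, seed = 1, sd = 0.05) {
  set.seed(seed)
  model@stages <- rapply(model@stages, function(x)
    x + rnorm(length(x), 0, sd), how = "replace")
  model
}
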