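#' Per-stage structural configuration
#'
#' Both domains use feature extractors of the same structure (they never
#' share parameters): \code{n_conv_layers} same-padded convolutions of
#' \code{kernel_size}, \code{n_channels} wide, ReLU activations, with a
#' linear final layer back to the 2 real channels carrying the complex
#' grid.
#'
#' @param n_conv_layers convolution layers per extractor (>= 2)
#' @param n_channels hidden channels
#' @param kernel_size odd kernel size
#' @param activation "relu"
#' @return validated list of class "stageConfig"
#' @export
stageConfig <- function(n_conv_layers = 3L, n_channels = 16L,
                        kernel_size = 3L, activation = "relu") {
  if (n_conv_layers < 2) stop("n_conv_layers must be >= 2")
  if (kernel_size %% 2 != 1) stop("kernel_size must be odd")
  activation <- match.arg(activation, "relu")
  list(n_conv_layers = as.integer(n_conv_layers),
       n_channels = as.integer(n_channels),
       kernel_size = as.integer(kernel_size), activation = activation)
}

#' Training configuration
#'
#' @param loss "mse" (mean squared error on the 2-channel complex image)
#' @param optimizer "adam"
#' @param learning_rate positive step size
#' @param epochs passes over the training set (>= 1)
#' @param batch_size samples per gradient step
#' @param seed integer seed controlling init order and shuffling
#' @return validated list of class "trainConfig"
#' @export
trainConfig <- function(loss = "mse", optimizer = "adam",
                        learning_rate = 1e-3, epochs = 10L, batch_size = 4L,
                        seed = 1L) {
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  if (epochs < 1) stop("epochs must be >= 1")
  list(loss = match.arg(loss, "mse"), optimizer = match.arg(optimizer, "adam"),
       learning_rate = learning_rate, epochs = as.integer(epochs),
       batch_size = as.integer(batch_size), seed = as.integer(seed))
}

# ---- parameter plumbing -----------------------------------------------------

# conv layer parameter init; fan-in He scaling, optionally zeroed
.initConv <- function(cin, cout, k, zero = FALSE) {
  nin <- k * k * cin
  w <- if (zero) matrix(0, nin, cout)
    else matrix(stats::rnorm(nin * cout, 0, sqrt(2 / nin)), nin, cout)
  list(w = w, b = numeric(cout))
}

# one stage's parameters; fusion convs and the stage-5 head start at zero so
# an untrained cascade is exactly the identity on the image chain
.initStage <- function(cfg, withHead = FALSE) {
  L <- cfg$n_conv_layers; C <- cfg$n_channels; k <- cfg$kernel_size
  plan <- c(2L, rep(C, L - 1L), 2L)
  mkNet <- function() lapply(seq_len(L), function(i)
    .initConv(plan[i], plan[i + 1], k))
  st <- list(imgNet = mkNet(), kNet = mkNet(),
             fuseImg = .initConv(4L, 2L, 1L, zero = TRUE),
             fuseK = .initConv(4L, 2L, 1L, zero = TRUE))
  if (withHead) st$head <- .initConv(2L, 2L, k, zero = TRUE)
  st
}

#' Build a five-stage dual-domain cascade model
#'
#' Stages 1-4 are structurally identical (image extractor, k-space
#' extractor with a data-consistency layer, cross-fusion, residual
#' connection); stage 5 additionally carries the output head that emits
#' the final reconstructed image. No parameters are shared between domains
#' or stages. Fusion convolutions start at zero, so the freshly built
#' cascade reproduces the zero-filled input exactly.
#'
#' @param config a \code{\link{stageConfig}}
#' @param fusion "conv" (learned 1x1 fusion) or "identity" (analytic
#'   fusion, used by structural tests)
#' @param dcLambda data-consistency weight; Inf (default) = hard
#' @param seed init seed
#' @return a \linkS4class{CascadeModel}
#' @export
buildCascadeModel <- function(config = stageConfig(), fusion = "conv",
                              dcLambda = Inf, seed = 1L) {
  old <- .Random.seed_exists()
  on.exit(restoreSeedState(old))
  set.seed(deriveSeed(seed, 17L))
  stages <- lapply(1:5, function(s) .initStage(config, withHead = s == 5L))
  new("CascadeModel", stages = stages, config = config, fusion = fusion,
      dcLambda = dcLambda)
}

#' Zero all residual branches of a model
#'
#' Sets every extractor, fusion and head weight to zero; the resulting
#' cascade is the identity map on the image chain (hard data consistency
#' still re-imposes measured samples on the k chain).
#'
#' @param model a \linkS4class{CascadeModel}
#' @return the zeroed model
#' @export
zeroResidualModel <- function(model) {
  model@stages <- rapply(model@stages, function(x) x * 0, how = "replace")
  model
}

# elementwise walk over two parallel nested parameter lists
.mapParams <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- .mapParams(a[[nm]], b[[nm]], f)
    out
  } else f(a, b)
}

# ---- forward / backward -----------------------------------------------------

.reluFwd <- function(x) { x[x < 0] <- 0; x }

.extractorFwd <- function(aChan, net, k) {
  acts <- vector("list", length(net) + 1)
  acts[[1]] <- aChan
  pre <- vector("list", length(net))
  x <- aChan
  for (i in seq_along(net)) {
    y <- conv2d_fwd(x, net[[i]]$w, net[[i]]$b, k)
    pre[[i]] <- y
    if (i < length(net)) y <- .reluFwd(y)
    x <- y
    acts[[i + 1]] <- x
  }
  list(out = x, acts = acts, pre = pre)
}

.extractorBwd <- function(cache, net, k, gy) {
  grads <- vector("list", length(net))
  for (i in rev(seq_along(net))) {
    if (i < length(net)) gy <- gy * (cache$pre[[i]] > 0)
    bw <- conv2d_bwd(cache$acts[[i]], net[[i]]$w, gy, k)
    grads[[i]] <- list(w = bw$gw, b = bw$gb)
    gy <- bw$gx
  }
  list(gx = gy, grads = grads)
}

# centered orthonormal transforms on bare complex matrices
.fwd <- function(z) fftshiftN(stats::fft(fftshiftN(z, inverse = TRUE))) /
  sqrt(length(z))
.inv <- function(z) fftshiftN(stats::fft(fftshiftN(z, inverse = TRUE),
                                         inverse = TRUE)) / sqrt(length(z))

# data consistency on a bare complex matrix + its gradient factor
.dcApply <- function(k, kMeas, keep, lam) {
  if (is.infinite(lam)) k[keep] <- kMeas[keep]
  else k[keep] <- (k[keep] + lam * kMeas[keep]) / (1 + lam)
  k
}
.dcFactor <- function(keep, lam) {
  f <- array(1, dim(keep))
  f[keep] <- if (is.infinite(lam)) 0 else 1 / (1 + lam)
  f
}

.cat2 <- function(a, b) array(c(a, b), c(dim(a)[1:2], 4L))

#' One cascade stage
#'
#' Image branch: feature extractor on the image input. k branch: feature
#' extractor on the k-space input followed by the data-consistency layer.
#' Cross-fusion augments each domain's features with the (inverse-)Fourier
#' view of the other domain's update before the fusion map, and the
#' residual connection adds the stage input.
#'
#' @param img complex image matrix (stage input, spatial domain)
#' @param k complex k-space matrix (stage input, frequency domain)
#' @param kMeas measured k-space (complex matrix)
#' @param keep logical sampling mask
#' @param stage one stage's parameter list
#' @param cfg the \code{\link{stageConfig}}
#' @param fusion "conv" or "identity"
#' @param lam data-consistency weight
#' @return list: \code{img}, \code{k} (stage outputs), \code{residual}
#'   (the image-domain residual-branch output added by Eq.-style skip),
#'   \code{cache} (for backprop)
#' @export
stageForward <- function(img, k, kMeas, keep, stage, cfg, fusion = "conv",
                         lam = Inf) {
  if (!identical(dim(img), dim(k)) || !identical(dim(img), dim(keep)))
    stop("stage input shapes must agree")
  ks <- cfg$kernel_size
  ei <- .extractorFwd(cplxToChan(img), stage$imgNet, ks)
  ek <- .extractorFwd(cplxToChan(k), stage$kNet, ks)
  xi <- ei$out                       # image-branch native update (2ch)
  kPlus <- k + chanToCplx(ek$out)
  kCons <- .dcApply(kPlus, kMeas, keep, lam)
  giC <- .inv(kCons) - img           # k-branch update seen in image domain
  gkC <- .fwd(chanToCplx(xi))        # image-branch update seen in k domain
  dkC <- kCons - k                   # k-branch native update
  if (fusion == "conv") {
    fi <- .cat2(xi, cplxToChan(giC))
    fk <- .cat2(cplxToChan(dkC), cplxToChan(gkC))
    ri <- conv2d_fwd(fi, stage$fuseImg$w, stage$fuseImg$b, 1L)
    rk <- conv2d_fwd(fk, stage$fuseK$w, stage$fuseK$b, 1L)
  } else {
    fi <- fk <- NULL
    ri <- xi + cplxToChan(giC)
    rk <- cplxToChan(dkC) + cplxToChan(gkC)
  }
  riC <- chanToCplx(ri)
  imgOut <- img + riC
  kOut <- .dcApply(k + chanToCplx(rk), kMeas, keep, lam)
  list(img = imgOut, k = kOut, residual = riC,
       cache = list(ei = ei, ek = ek, xi = xi, kPlus = kPlus, kCons = kCons,
                    giC = giC, dkC = dkC, fi = fi, fk = fk, img = img,
                    k = k))
}

# backward through one stage; gImg/gK are complex gradient grids w.r.t. the
# stage outputs. Returns input gradients + parameter gradients.
.stageBackward <- function(st, cfg, fusion, lam, keep, cache, gImg, gK) {
  ks <- cfg$kernel_size
  fac <- .dcFactor(keep, lam)
  gKin <- fac * gK                      # k_out = DC(k + rk)
  gRk <- cplxToChan(fac * gK)
  gImgIn <- gImg                        # img_out = img + ri
  gRi <- cplxToChan(gImg)
  if (fusion == "conv") {
    bi <- conv2d_bwd(cache$fi, st$fuseImg$w, gRi, 1L)
    bk <- conv2d_bwd(cache$fk, st$fuseK$w, gRk, 1L)
    gXi <- bi$gx[, , 1:2, drop = FALSE]
    gGi <- chanToCplx(bi$gx[, , 3:4, drop = FALSE])
    gDk <- chanToCplx(bk$gx[, , 1:2, drop = FALSE])
    gGk <- chanToCplx(bk$gx[, , 3:4, drop = FALSE])
    gFuseImg <- list(w = bi$gw, b = bi$gb)
    gFuseK <- list(w = bk$gw, b = bk$gb)
  } else {
    gXi <- gRi
    gGi <- chanToCplx(gRi)
    gDk <- chanToCplx(gRk)
    gGk <- chanToCplx(gRk)
    gFuseImg <- list(w = st$fuseImg$w * 0, b = st$fuseImg$b * 0)
    gFuseK <- list(w = st$fuseK$w * 0, b = st$fuseK$b * 0)
  }
  # gk = FFT(xi): adjoint is the inverse transform
  gXi <- gXi + cplxToChan(.inv(gGk))
  # dk = kCons - k ; gi = IFFT(kCons) - img
  gKcons <- gDk + .fwd(gGi)
  gKin <- gKin - gDk
  gImgIn <- gImgIn - gGi
  # kCons = DC(k + E_k(k))
  gKplus <- fac * gKcons
  gKin <- gKin + gKplus
  bek <- .extractorBwd(cache$ek, st$kNet, ks, cplxToChan(gKplus))
  gKin <- gKin + chanToCplx(bek$gx)
  bei <- .extractorBwd(cache$ei, st$imgNet, ks, gXi)
  gImgIn <- gImgIn + chanToCplx(bei$gx)
  list(gImg = gImgIn, gK = gKin,
       grads = list(imgNet = bei$grads, kNet = bek$grads,
                    fuseImg = gFuseImg, fuseK = gFuseK))
}

#' Run the full cascade
#'
#' Stage 1 receives the zero-filled image and the measured k-space; the
#' five stages are chained; the stage-5 output head emits the final image,
#' which then passes through one terminal data-consistency application.
#'
#' @param model a \linkS4class{CascadeModel}
#' @param kMeas measured \linkS4class{KSpace} (or complex matrix), already
#'   masked
#' @param mask a \linkS4class{SamplingMask} (or logical matrix)
#' @param record keep per-stage outputs and residual-branch outputs?
#' @return a \linkS4class{ComplexImage}; with \code{record = TRUE} a list
#'   with \code{image}, \code{input} (zero-filled stage-1 input),
#'   \code{residuals} (per-stage image-domain residual outputs),
#'   \code{stageK} (per-stage k outputs)
#' @export
cascadeForward <- function(model, kMeas, mask, record = FALSE) {
  km <- if (is(kMeas, "KSpace")) kMeas@values else kMeas
  sp <- if (is(kMeas, "KSpace")) kMeas@spacing else rep(1, 2)
  keep <- if (is(mask, "SamplingMask")) maskKeep(mask) else mask
  fw <- .cascadeFwdFull(model, km, keep)
  if (record)
    list(image = new("ComplexImage", values = fw$out, spacing = sp),
         input = fw$img0, residuals = fw$residuals, stageK = fw$stageK,
         stageImg = fw$stageImg)
  else new("ComplexImage", values = fw$out, spacing = sp)
}

# full forward with caches (internal; used by training and backprop)
.cascadeFwdFull <- function(model, km, keep) {
  lam <- model@dcLambda; cfg <- model@config; fus <- model@fusion
  z <- km
  z[!keep] <- 0 + 0i
  img <- .inv(z)                      # zero-filled stage-1 input
  k <- km
  caches <- vector("list", 5)
  residuals <- vector("list", 5)
  stageK <- vector("list", 5); stageImg <- vector("list", 5)
  img0 <- img
  for (s in 1:5) {
    sf <- stageForward(img, k, km, keep, model@stages[[s]], cfg, fus, lam)
    caches[[s]] <- sf$cache
    residuals[[s]] <- sf$residual
    img <- sf$img; k <- sf$k
    stageK[[s]] <- k; stageImg[[s]] <- img
  }
  headIn <- cplxToChan(img)
  h <- conv2d_fwd(headIn, model@stages[[5]]$head$w,
                  model@stages[[5]]$head$b, cfg$kernel_size)
  imgPre <- img + chanToCplx(h)
  kFin <- .dcApply(.fwd(imgPre), km, keep, lam)
  out <- .inv(kFin)
  list(out = out, img0 = img0, caches = caches, residuals = residuals,
       stageK = stageK, stageImg = stageImg, headIn = headIn,
       imgPre = imgPre)
}

# backward through the whole cascade; gOut is the complex gradient grid
# w.r.t. the output image. Returns parameter gradients and the gradient
# w.r.t. the stage-1 image input (treating k1 = FFT(img1)).
.cascadeBwdFull <- function(model, km, keep, fw, gOut, inputIsFree = FALSE) {
  lam <- model@dcLambda; cfg <- model@config; fus <- model@fusion
  fac <- .dcFactor(keep, lam)
  gKfin <- .fwd(gOut)
  gImgPre <- .inv(fac * gKfin)
  hb <- conv2d_bwd(fw$headIn, model@stages[[5]]$head$w,
                   cplxToChan(gImgPre), cfg$kernel_size)
  gImg <- gImgPre + chanToCplx(hb$gx)
  gK <- array(0 + 0i, dim(km))
  grads <- vector("list", 5)
  for (s in 5:1) {
    sb <- .stageBackward(model@stages[[s]], cfg, fus, lam, keep,
                         fw$caches[[s]], gImg, gK)
    grads[[s]] <- sb$grads
    gImg <- sb$gImg; gK <- sb$gK
  }
  grads[[5]]$head <- list(w = hb$gw, b = hb$gb)
  gInput <- if (inputIsFree) gImg + .inv(gK) else gImg
  list(grads = grads, gInput = gInput)
}

# ---- training ---------------------------------------------------------------

.mseLossGrad <- function(out, target) {
  d <- out - target
  n <- 2 * length(d)   # 2 real channels
  list(loss = sum(Re(d)^2 + Im(d)^2) / n, g = 2 * d / n)
}

#' Train the cascade on (k-space, mask, ground truth) samples
#'
#' Adam on mean-squared error over the 2-channel complex image. Aborts with
#' a diagnostic if the loss becomes non-finite. Identical seeds reproduce
#' identical loss histories.
#'
#' @param model a \linkS4class{CascadeModel}
#' @param dataset list of samples; each a list with \code{kMeas} (complex
#'   matrix or KSpace), \code{mask} (SamplingMask or logical matrix), and
#'   \code{target} (complex matrix or ComplexImage)
#' @param cfg a \code{\link{trainConfig}}
#' @return list: \code{model} (trained), \code{history} (per-step training
#'   loss)
#' @export
trainCascade <- function(model, dataset, cfg = trainConfig()) {
  stopifnot(length(dataset) >= 1)
  old <- .Random.seed_exists()
  on.exit(restoreSeedState(old))
  set.seed(deriveSeed(cfg$seed, 23L))
  samples <- lapply(dataset, function(s) list(
    km = if (is(s$kMeas, "KSpace")) s$kMeas@values else s$kMeas,
    keep = if (is(s$mask, "SamplingMask")) maskKeep(s$mask) else s$mask,
    target = if (is(s$target, "ComplexImage")) s$target@values else s$target))
  params <- model@stages
  mAdam <- rapply(params, function(x) x * 0, how = "replace")
  vAdam <- rapply(params, function(x) x * 0, how = "replace")
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t <- 0L
  history <- numeric(0)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(length(samples))
    for (bs in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      t <- t + 1L
      gAcc <- NULL
      lossAcc <- 0
      for (i in bs) {
        s <- samples[[i]]
        fw <- .cascadeFwdFull(model, s$km, s$keep)
        lg <- .mseLossGrad(fw$out, s$target)
        lossAcc <- lossAcc + lg$loss
        bw <- .cascadeBwdFull(model, s$km, s$keep, fw, lg$g)
        gAcc <- if (is.null(gAcc)) bw$grads
          else .mapParams(gAcc, bw$grads, `+`)
      }
      loss <- lossAcc / length(bs)
      if (!is.finite(loss))
        stop("training diverged at step ", t, ": non-finite loss")
      history <- c(history, loss)
      if (cfg$learning_rate > 0) {
        gAcc <- rapply(gAcc, function(x) x / length(bs), how = "replace")
        mAdam <- .mapParams(mAdam, gAcc, function(m, g) b1 * m + (1 - b1) * g)
        vAdam <- .mapParams(vAdam, gAcc, function(v, g) b2 * v + (1 - b2) * g^2)
        mh <- rapply(mAdam, function(x) x / (1 - b1^t), how = "replace")
        vh <- rapply(vAdam, function(x) x / (1 - b2^t), how = "replace")
        step <- .mapParams(mh, vh, function(m, v)
          cfg$learning_rate * m / (sqrt(v) + eps))
        model@stages <- .mapParams(model@stages, step, `-`)
      }
    }
  }
  list(model = model, history = history)
}

#' Gradient-flow report for the residual cascade
#'
#' Verifies the identity-path property of the residual formulation: with
#' all residual branches zeroed, the loss gradient with respect to the
#' cascade input equals the gradient with respect to its output (the
#' identity term of the chain rule); with random weights the input
#' gradient is still non-vanishing. The check runs with data consistency
#' disabled (lambda = 0) so the skip path is isolated from the sampling
#' projection.
#'
#' @param model a \linkS4class{CascadeModel}
#' @param shape 2D grid shape for the probe
#' @param seed RNG seed for the probe input/target
#' @return list: \code{zeroed_gap} (max abs difference between input and
#'   output gradients for the zeroed model), \code{input_grad_norm}
#'   (gradient norm through the supplied model), \code{pass}
#' @export
gradientFlowCheck <- function(model, shape = c(32L, 32L), seed = 1L) {
  old <- .Random.seed_exists()
  on.exit(restoreSeedState(old))
  set.seed(deriveSeed(seed, 29L))
  x <- matrix(complex(real = stats::rnorm(prod(shape)),
                      imaginary = stats::rnorm(prod(shape))),
              shape[1], shape[2])
  target <- matrix(complex(real = stats::rnorm(prod(shape)),
                           imaginary = stats::rnorm(prod(shape))),
                   shape[1], shape[2])
  keep <- matrix(TRUE, shape[1], shape[2])
  probe <- function(m) {
    m@dcLambda <- 0   # disable consistency: isolate the residual path
    km <- .fwd(x)
    fw <- .cascadeFwdFull(m, km, keep)
    lg <- .mseLossGrad(fw$out, target)
    bw <- .cascadeBwdFull(m, km, keep, fw, lg$g, inputIsFree = TRUE)
    list(gIn = bw$gInput, gOut = lg$g)
  }
  z <- probe(zeroResidualModel(model))
  r <- probe(model)
  list(zeroed_gap = max(Mod(z$gIn - z$gOut)),
       input_grad_norm = sqrt(sum(Mod(r$gIn)^2)),
       pass = max(Mod(z$gIn - z$gOut)) < 1e-6 &&
         sqrt(sum(Mod(r$gIn)^2)) > 0)
}

# ---- evaluation -------------------------------------------------------------

#' Peak signal-to-noise ratio (dB) on magnitude images
#'
#' Peak taken from the reference; identical inputs give \code{Inf}.
#'
#' @param x reconstruction (complex or real array / ComplexImage)
#' @param ref ground truth
#' @return PSNR in dB
#' @export
psnr <- function(x, ref) {
  xv <- Mod(if (is(x, "ComplexImage")) x@values else x)
  rv <- Mod(if (is(ref, "ComplexImage")) ref@values else ref)
  mse <- mean((xv - rv)^2)
  if (mse == 0) return(Inf)
  20 * log10(max(rv) / sqrt(mse))
}

#' Structural similarity index on magnitude images
#'
#' Standard single-scale SSIM with an 11-point Gaussian window
#' (sigma 1.5), dynamic range from the reference.
#'
#' @param x reconstruction
#' @param ref ground truth
#' @return mean SSIM in [-1, 1]
#' @export
ssim <- function(x, ref) {
  xv <- Mod(if (is(x, "ComplexImage")) x@values else x)
  rv <- Mod(if (is(ref, "ComplexImage")) ref@values else ref)
  L <- max(rv) - min(rv)
  if (L == 0) L <- 1
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  g <- stats::dnorm(seq(-5, 5), 0, 1.5)
  g <- g / sum(g)
  smooth <- function(im) {
    t(apply(apply(im, 2, stats::filter, filter = g, sides = 2), 1,
            stats::filter, filter = g, sides = 2))
  }
  mx <- smooth(xv); mr <- smooth(rv)
  ok <- !is.na(mx) & !is.na(mr)
  sxx <- smooth(xv * xv) - mx^2
  srr <- smooth(rv * rv) - mr^2
  sxr <- smooth(xv * rv) - mx * mr
  s <- ((2 * mx * mr + c1) * (2 * sxr + c2)) /
    ((mx^2 + mr^2 + c1) * (sxx + srr + c2))
  mean(s[ok])
}

#' Evaluate a model against the zero-filled baseline
#'
#' @param model a \linkS4class{CascadeModel}
#' @param testset list of samples (as in \code{\link{trainCascade}})
#' @return data.frame with per-sample PSNR/SSIM for the reconstruction and
#'   the zero-filled baseline, plus a "mean" summary row
#' @export
evaluateRecon <- function(model, testset) {
  if (!length(testset)) stop("empty test set")
  rows <- lapply(seq_along(testset), function(i) {
    s <- testset[[i]]
    km <- if (is(s$kMeas, "KSpace")) s$kMeas@values else s$kMeas
    keep <- if (is(s$mask, "SamplingMask")) maskKeep(s$mask) else s$mask
    target <- if (is(s$target, "ComplexImage")) s$target@values else s$target
    rec <- cascadeForward(model, km, keep)@values
    zf <- km; zf[!keep] <- 0 + 0i
    zfi <- .inv(zf)
    data.frame(sample = i,
               psnr_recon = psnr(rec, target), ssim_recon = ssim(rec, target),
               psnr_zf = psnr(zfi, target), ssim_zf = ssim(zfi, target))
  })
  tab <- do.call(rbind, rows)
  summary <- data.frame(sample = NA,
                        psnr_recon = mean(tab$psnr_recon),
                        ssim_recon = mean(tab$ssim_recon),
                        psnr_zf = mean(tab$psnr_zf),
                        ssim_zf = mean(tab$ssim_zf))
  rbind(tab, summary)
}
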