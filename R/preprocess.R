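## Projection pre-processing: flat-field correction, Beer-Lambert inversion,
## dead-pixel inpainting and ring suppression on the sinogram.

#' Flat-field correction
#'
#' Converts raw detector counts to transmittance
#' T = (raw - dark) / (flat - dark), clamped to (eps, 1 + delta]. The small
#' positive floor keeps the subsequent logarithm finite in fully opaque
#' pixels; the upper slack tolerates noise overshoot above the empty-beam
#' level.
#'
#' @param raw numeric array (nu, nv, nAngles) or matrix of counts
#' @param flat,dark reference frames (nu, nv)
#' @param eps lower clamp for transmittance
#' @param delta upper slack above 1
#' @return transmittance array in `[eps, 1 + delta]`
#' @export
flatFieldCorrect <- function(raw, flat, dark, eps = 1e-6, delta = 0.5) {
    bad <- sum(flat <= dark)
    if (bad > 0)
        stop("flat field does not exceed dark field at ", bad, " pixel(s)")
    denom <- as.numeric(flat - dark)
    d <- dim(raw)
    tr <- (as.numeric(raw) - as.numeric(dark)) / denom  # recycles per frame
    tr <- pmin(pmax(tr, eps), 1 + delta)
    dim(tr) <- d
    tr
}

#' Beer-Lambert inversion to line integrals
#'
#' p = -log(T). The flat-field clamp guarantees positivity of T, so p is
#' finite and bounded below by -log(1 + delta).
#'
#' @param transmittance array from [flatFieldCorrect()]
#' @return sinogram array of line integrals
#' @export
toLineIntegrals <- function(transmittance) {
    if (any(transmittance <= 0))
        stop("non-positive transmittance; apply flatFieldCorrect() first")
    -log(transmittance)
}

#' Dead-pixel inpainting keyed on the flat field
#'
#' Detector pixels whose flat-field value deviates by more than
#' `nSigma` robust standard deviations from their 3 x 3 local median are
#' treated as defective and replaced by that local median in the flat, the
#' dark and every projection frame.
#'
#' @param raw projection array (nu, nv, nAngles)
#' @param flat,dark reference frames
#' @param nSigma outlier threshold in robust sd units
#' @return list(raw, flat, dark, nBad)
#' @export
deadPixelInpaint <- function(raw, flat, dark, nSigma = 5) {
    med <- localMedian3(flat)
    resid <- flat - med
    s <- stats::mad(resid)
    if (s == 0) s <- sd(resid)
    if (is.na(s) || s == 0)
        return(list(raw = raw, flat = flat, dark = dark, nBad = 0L))
    bad <- which(abs(resid) > nSigma * s)
    if (length(bad)) {
        flat[bad] <- med[bad]
        medD <- localMedian3(dark)
        dark[bad] <- medD[bad]
        for (k in seq_len(dim(raw)[3])) {
            fr <- raw[, , k]
            mf <- localMedian3(fr)
            fr[bad] <- mf[bad]
            raw[, , k] <- fr
        }
    }
    list(raw = raw, flat = flat, dark = dark, nBad = length(bad))
}

## 3x3 local median with edge replication, vectorized via shifted copies
localMedian3 <- function(m) {
    n1 <- nrow(m); n2 <- ncol(m)
    ri <- cbind(c(1, seq_len(n1 - 1)), seq_len(n1), c(seq_len(n1 - 1) + 1, n1))
    ci <- cbind(c(1, seq_len(n2 - 1)), seq_len(n2), c(seq_len(n2 - 1) + 1, n2))
    stackm <- vapply(1:3, function(i) vapply(1:3, function(j)
        m[ri[, i], ci[, j]], m), array(0, c(n1, n2, 3)))
    dim(stackm) <- c(n1 * n2, 9)
    med <- apply(stackm, 1, median)
    matrix(med, n1, n2)
}

#' Ring-artifact suppression on the sinogram
#'
#' For every detector row v, the angle-averaged column profile is computed,
#' median-smoothed with an odd kernel, and the high-frequency residual
#' (profile minus smoothed profile) is subtracted from all angles. Static
#' per-column gain errors are removed while genuine object structure, which
#' varies with angle and spans many columns, survives.
#'
#' @param sinogram array (nu, nv, nAngles) of line integrals
#' @param kernelWidth odd smoothing width >= 3 (detector columns)
#' @return corrected sinogram of the same shape
#' @export
ringFilter <- function(sinogram, kernelWidth = 9) {
    if (kernelWidth < 3 || kernelWidth %% 2 == 0)
        stop("kernelWidth must be odd and >= 3")
    d <- dim(sinogram)
    out <- sinogram
    for (v in seq_len(d[2])) {
        prof <- rowMeans(sinogram[, v, , drop = FALSE], dims = 1)
        smooth <- stats::runmed(prof, kernelWidth, endrule = "median")
        resid <- prof - smooth
        out[, v, ] <- sinogram[, v, ] - resid
    }
    out
}
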