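## REML engine for variance-component models y = Xb + Z1 u1 + ... + e with
## independent random terms (one variance each), via the sparse mixed-model
## equations.  The restricted log-likelihood is maximized directly over
## log variance ratios (residual profiled out), with non-negativity implied
## by the log parameterization and multiple starts against local optima.
## Standard errors come from the curvature of the restricted likelihood in
## the variance components (delta-free, finite differences).

#' @importFrom Matrix Diagonal sparseMatrix forceSymmetric crossprod t solve determinant
NULL

.sparseIndicator <- function(f) {
    f <- factor(f)
    Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                         dims = c(length(f), nlevels(f)),
                         dimnames = list(NULL, levels(f)))
}

.remlPrep <- function(y, X, Zlist) {
    X <- as.matrix(X)
    qrX <- qr(X)
    aliased <- character()
    if (qrX$rank < ncol(X)) {
        keep <- sort(qrX$pivot[seq_len(qrX$rank)])
        aliased <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
        X <- X[, keep, drop = FALSE]
    }
    Z <- do.call(cbind, lapply(Zlist, methods::as, "CsparseMatrix"))
    qk <- vapply(Zlist, ncol, integer(1L))
    W <- cbind(methods::as(X, "CsparseMatrix"), Z)
    list(y = y, X = X, Z = Z, qk = qk, n = length(y), p = ncol(X),
         K = length(Zlist), termNames = names(Zlist), aliased = aliased,
         WtW = Matrix::forceSymmetric(Matrix::crossprod(W)),
         Xty = crossprod(X, y)[, 1L], XtX = crossprod(X),
         Zty = Matrix::crossprod(Z, y)[, 1L], yty = sum(y * y))
}

# core evaluation at variance ratios gamma; returns pieces of -2 REML
.remlCore <- function(gamma, prep) {
    dinv <- rep(1 / gamma, prep$qk)
    C <- prep$WtW + Matrix::Diagonal(x = c(rep(0, prep$p), dinv))
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(C), LDL = FALSE,
                           perm = TRUE)
    ld <- 2 * Matrix::determinant(ch, sqrt = TRUE)$modulus
    rhs <- c(prep$Xty, prep$Zty)
    sol <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
    quad <- prep$yty - sum(rhs * sol)
    list(logdetC = as.numeric(ld), quad = max(quad, 1e-300),
         sol = sol, C = C, ch = ch)
}

.remlObjProfiled <- function(loggamma, prep) {
    core <- tryCatch(.remlCore(exp(loggamma), prep), error = function(e) NULL)
    if (is.null(core)) return(1e10)
    np <- prep$n - prep$p
    sigma2e <- core$quad / np
    np * log(sigma2e) + sum(prep$qk * loggamma) + core$logdetC + np
}

# analytic gradient of the profiled criterion w.r.t. log gamma
.remlGradProfiled <- function(loggamma, prep) {
    gamma <- exp(loggamma)
    core <- tryCatch(.remlCore(gamma, prep), error = function(e) NULL)
    if (is.null(core)) return(rep(0, length(gamma)))
    np <- prep$n - prep$p
    blk <- rep(seq_len(prep$K), prep$qk)
    uIdx <- prep$p + seq_len(sum(prep$qk))
    Cinv <- Matrix::solve(core$ch, Matrix::Diagonal(prep$p + sum(prep$qk)),
                          system = "A")
    dC <- Matrix::diag(Cinv)[uIdx]
    u2 <- core$sol[uIdx]^2
    g <- numeric(prep$K)
    for (k in seq_len(prep$K)) {
        sel <- blk == k
        trk <- sum(dC[sel])
        ## d/dgamma_k of: logdetC  = -(1/gamma^2) tr(Cinv_kk)
        ##                y'P*y    = +(1/gamma^2) sum(u_k^2)  (note sign)
        dlogdetC <- -trk / gamma[k]^2
        dquad <- -sum(u2[sel]) / gamma[k]^2
        dval <- np * dquad / core$quad + prep$qk[k] / gamma[k] + dlogdetC
        g[k] <- dval * gamma[k]            # chain rule to log scale
    }
    g
}

# -2 REML as a function of the full variance vector (components..., residual)
.remlObjFull <- function(sig2, prep) {
    K <- prep$K
    s2e <- sig2[K + 1L]
    gamma <- sig2[seq_len(K)] / s2e
    core <- .remlCore(gamma, prep)
    np <- prep$n - prep$p
    np * log(s2e) + sum(prep$qk * log(gamma)) + core$logdetC + core$quad / s2e
}

.remlFit <- function(y, X, Zlist, starts = NULL, computeSE = TRUE,
                     fast = FALSE) {
    prep <- .remlPrep(y, X, Zlist)
    K <- prep$K
    if (K == 0L) {                        # pure fixed-effects model
        b <- qr.coef(qr(prep$X), y)
        res <- y - prep$X %*% b
        s2e <- sum(res^2) / (prep$n - prep$p)
        covB <- s2e * solve(prep$XtX)
        return(list(sigma2 = c(residual = s2e), se = c(residual = NA_real_),
                    beta = b, covBeta = covB, prep = prep,
                    logLik = NA_real_, converged = TRUE))
    }
    if (is.null(starts))
        starts <- if (fast) list(rep(log(0.2), K))
                  else list(rep(log(0.5), K), rep(log(0.05), K),
                            rep(log(2), K))
    ctrl <- if (fast) list(maxit = 150, factr = 1e9, ndeps = rep(1e-4, K))
            else list(maxit = 500, factr = 1e4, pgtol = 1e-8)
    gr <- if (fast) NULL else .remlGradProfiled
    best <- NULL
    conv <- FALSE
    for (s0 in starts) {
        o <- tryCatch(
            optim(s0, .remlObjProfiled, gr = gr, prep = prep,
                  method = "L-BFGS-B",
                  lower = rep(-16, K), upper = rep(16, K),
                  control = ctrl),
            error = function(e) NULL)
        if (is.null(o)) next
        if (is.null(best) || o$value < best$value - 1e-9) {
            best <- o
            conv <- o$convergence == 0L
        }
    }
    if (is.null(best)) stop("REML optimization failed")
    if (!fast) {          # polish to tight tolerance from the best optimum
        o2 <- tryCatch(
            optim(best$par, .remlObjProfiled, gr = .remlGradProfiled,
                  prep = prep, method = "L-BFGS-B", lower = rep(-16, K),
                  upper = rep(16, K),
                  control = list(maxit = 200, factr = 10, pgtol = 1e-11)),
            error = function(e) NULL)
        if (!is.null(o2) && o2$value <= best$value) best <- o2
    }
    gamma <- exp(best$par)
    core <- .remlCore(gamma, prep)
    np <- prep$n - prep$p
    s2e <- core$quad / np
    sigma2 <- c(gamma * s2e, s2e)
    names(sigma2) <- c(prep$termNames, "residual")
    ## zero-boundary clean-up
    sigma2[seq_len(K)][gamma < 1e-7] <- 0
    beta <- core$sol[seq_len(prep$p)]
    names(beta) <- colnames(prep$X)
    Cinv1 <- Matrix::solve(core$ch,
                           rbind(diag(prep$p),
                                 matrix(0, sum(prep$qk), prep$p)),
                           system = "A")
    covBeta <- s2e * as.matrix(Cinv1[seq_len(prep$p), , drop = FALSE])
    dimnames(covBeta) <- list(names(beta), names(beta))
    ll <- -0.5 * (best$value + np * log(2 * pi))
    se <- if (computeSE) .remlComponentSE(sigma2, prep)
          else setNames(rep(NA_real_, K + 1L), names(sigma2))
    list(sigma2 = sigma2, se = se, beta = beta, covBeta = covBeta,
         prep = prep, logLik = ll, converged = conv,
         neg2REML = best$value)
}

.remlComponentSE <- function(sig2, prep) {
    K <- prep$K
    th <- sig2
    free <- th > 1e-7 * max(th, 1)
    se <- rep(NA_real_, K + 1L)
    idx <- which(free)
    m <- length(idx)
    if (m == 0L) return(setNames(se, names(sig2)))
    f <- function(x) {
        v <- th; v[idx] <- x
        .remlObjFull(pmax(v, 1e-12), prep)
    }
    h <- pmax(abs(th[idx]) * 1e-3, 1e-6)
    H <- matrix(NA_real_, m, m)
    f0 <- f(th[idx])
    for (a in seq_len(m)) {
        for (b in a:m) {
            if (a == b) {
                xp <- th[idx]; xp[a] <- xp[a] + h[a]
                xm <- th[idx]; xm[a] <- xm[a] - h[a]
                H[a, a] <- (f(xp) - 2 * f0 + f(xm)) / h[a]^2
            } else {
                xpp <- th[idx]; xpp[a] <- xpp[a] + h[a]; xpp[b] <- xpp[b] + h[b]
                xpm <- th[idx]; xpm[a] <- xpm[a] + h[a]; xpm[b] <- xpm[b] - h[b]
                xmp <- th[idx]; xmp[a] <- xmp[a] - h[a]; xmp[b] <- xmp[b] + h[b]
                xmm <- th[idx]; xmm[a] <- xmm[a] - h[a]; xmm[b] <- xmm[b] - h[b]
                H[a, b] <- H[b, a] <-
                    (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[a] * h[b])
            }
        }
    }
    V <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(V)) {
        d <- diag(V)
        se[idx] <- ifelse(d > 0, sqrt(d), NA_real_)
    }
    setNames(se, names(sig2))
}

# Joint Wald statistic for a set of fixed-effect coefficients
.waldJoint <- function(fit, cols) {
    cols <- intersect(cols, names(fit$beta))
    if (!length(cols)) return(list(stat = NA_real_, df = 0L))
    b <- fit$beta[cols]
    V <- fit$covBeta[cols, cols, drop = FALSE]
    st <- tryCatch(drop(t(b) %*% solve(V, b)), error = function(e) NA_real_)
    list(stat = st, df = length(cols))
}

## ---------------------------------------------------------------------------
## Bivariate REML: two traits, unstructured genotype and residual covariance,
## diagonal replicate covariance; log-Cholesky parameterization.

.lchol2 <- function(par3) {
    L <- matrix(c(exp(par3[1L]), par3[2L], 0, exp(par3[3L])), 2, 2)
    L %*% t(L)
}

.bivPrep <- function(data, trait1, trait2, markerEffects = NULL) {
    d1 <- data[data$trait == trait1 & !is.na(data$value), ]
    d2 <- data[data$trait == trait2 & !is.na(data$value), ]
    m <- merge(d1, d2, by = c("genotype", "location", "replicate"),
               suffixes = c(".1", ".2"))
    if (length(unique(m$genotype)) < 3L)
        stop("fewer than 3 genotypes with complete trait pairs")
    np <- nrow(m)
    y <- as.vector(rbind(m$value.1, m$value.2))      # plot-major, trait-minor
    trait <- rep(1:2, np)
    plot_ <- rep(seq_len(np), each = 2L)
    geno <- factor(m$genotype)
    rep_ <- factor(paste(m$location, m$replicate, sep = ":"))
    g <- nlevels(geno); r <- nlevels(rep_)
    ## genotype x trait columns grouped by genotype: (g1t1, g1t2, g2t1, ...)
    jg <- (as.integer(geno)[plot_] - 1L) * 2L + trait
    Zg <- Matrix::sparseMatrix(i = seq_along(y), j = jg, x = 1,
                               dims = c(length(y), 2L * g))
    jr <- (as.integer(rep_)[plot_] - 1L) * 2L + trait
    Zr <- Matrix::sparseMatrix(i = seq_along(y), j = jr, x = 1,
                               dims = c(length(y), 2L * r))
    X <- cbind(`(Intercept):1` = as.numeric(trait == 1L),
               `(Intercept):2` = as.numeric(trait == 2L))
    if (!is.null(markerEffects)) {
        me <- markerEffects[match(m$genotype, rownames(markerEffects)), ,
                            drop = FALSE]
        for (cn in colnames(markerEffects)) {
            v <- me[plot_, cn]
            X <- cbind(X, v * (trait == 1L), v * (trait == 2L))
            colnames(X)[ncol(X) - 1:0] <- paste(cn, 1:2, sep = ":")
        }
    }
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
        X <- X[, sort(qrX$pivot[seq_len(qrX$rank)]), drop = FALSE]
    ## per-trait blocks: any weighted cross-product M' (I x Einv) N equals
    ## sum_{t,u} Einv[t,u] * crossprod(M_t, N_u) with rows aligned by plot.
    ## All pieces are pre-aligned onto one upper-triangular sparsity pattern
    ## so an evaluation is a weighted numeric sum, one numeric Cholesky
    ## refactorization on a fixed symbolic analysis, and two 2x2 solves.
    W <- cbind(methods::as(X, "CsparseMatrix"), Zg, Zr)
    p <- ncol(X); q <- ncol(Zg) + ncol(Zr)
    rows <- list(which(trait == 1L), which(trait == 2L))
    cp <- function(i, j) Matrix::crossprod(W[i, , drop = FALSE],
                                           W[j, , drop = FALSE])
    K11 <- cp(rows[[1L]], rows[[1L]])
    K22 <- cp(rows[[2L]], rows[[2L]])
    K12 <- cp(rows[[1L]], rows[[2L]])
    Ksym <- K12 + Matrix::t(K12)
    vy <- function(i, j) as.numeric(Matrix::crossprod(W[i, , drop = FALSE],
                                                      y[j]))
    v11 <- vy(rows[[1L]], rows[[1L]]); v22 <- vy(rows[[2L]], rows[[2L]])
    vsym <- vy(rows[[1L]], rows[[2L]]) + vy(rows[[2L]], rows[[1L]])
    y11 <- sum(y[rows[[1L]]]^2); y22 <- sum(y[rows[[2L]]]^2)
    ysym <- 2 * sum(y[rows[[1L]]] * y[rows[[2L]]])
    ## upper-triangular template for G^{-1} (per-genotype 2x2) + R^{-1}
    b0 <- seq(1L, 2L * g, by = 2L)
    giU <- p + c(rep(b0, each = 3L) + c(0L, 0L, 1L),
                 2L * g + seq_len(2L * r))
    gjU <- p + c(rep(b0, each = 3L) + c(0L, 1L, 1L),
                 2L * g + seq_len(2L * r))
    Gpat <- Matrix::sparseMatrix(i = giU, j = gjU, x = 1,
                                 dims = rep(p + q, 2L))
    A0 <- Matrix::forceSymmetric(
        K11 + K22 + Ksym + Gpat + Matrix::t(Gpat), uplo = "U")
    alignVec <- function(M) {
        M <- methods::as(Matrix::forceSymmetric(M, uplo = "U"), "CsparseMatrix")
        out <- numeric(length(A0@x))
        for (cc in seq_len(ncol(A0))) {
            a0 <- A0@p[cc]; a1 <- A0@p[cc + 1L]
            m0 <- M@p[cc]; m1 <- M@p[cc + 1L]
            if (m1 > m0)
                out[a0 + match(M@i[(m0 + 1L):m1], A0@i[(a0 + 1L):a1])] <-
                    M@x[(m0 + 1L):m1]
        }
        out
    }
    x11 <- alignVec(K11); x22 <- alignVec(K22); xsym <- alignVec(Ksym)
    gmarks <- alignVec(Matrix::sparseMatrix(i = giU, j = gjU,
                                            x = seq_along(giU),
                                            dims = rep(p + q, 2L)))
    gmap <- integer(length(giU))
    nz <- which(gmarks != 0)
    gmap[gmarks[nz]] <- nz
    Cs0 <- A0
    x0 <- x11 + x22
    x0[gmap] <- x0[gmap] + c(rep(c(1, 0, 1), g), rep(1, 2L * r))
    Cs0@x <- x0                          # a PD member of the pattern
    ch0 <- Matrix::Cholesky(Cs0, LDL = FALSE, perm = TRUE)
    list(y = y, X = X, nPlot = np, g = g, r = r,
         trait = trait, plot = plot_, p = p, q = q,
         A0 = A0, ch0 = ch0, x11 = x11, x22 = x22, xsym = xsym,
         gmap = gmap, v11 = v11, v22 = v22, vsym = vsym,
         y11 = y11, y22 = y22, ysym = ysym)
}

.bivNeg2REML <- function(par, bp, zeroCov = FALSE) {
    if (zeroCov) {
        full <- c(par[1L], 0, par[2L], par[3L], par[4L], par[5L], 0, par[6L])
    } else full <- par
    SG <- .lchol2(full[1:3])
    vr <- exp(full[4:5])
    SE <- .lchol2(full[6:8])
    dSE <- SE[1L, 1L] * SE[2L, 2L] - SE[1L, 2L]^2
    dSG <- SG[1L, 1L] * SG[2L, 2L] - SG[1L, 2L]^2
    if (!is.finite(dSE) || dSE <= 0 || !is.finite(dSG) || dSG <= 0)
        return(1e10)
    e11 <- SE[2L, 2L] / dSE; e22 <- SE[1L, 1L] / dSE
    e12 <- -SE[1L, 2L] / dSE
    s11 <- SG[2L, 2L] / dSG; s22 <- SG[1L, 1L] / dSG
    s12 <- -SG[1L, 2L] / dSG
    xC <- e11 * bp$x11 + e22 * bp$x22 + e12 * bp$xsym
    gx <- c(rep(c(s11, s12, s22), bp$g), rep(1 / vr, bp$r))
    xC[bp$gmap] <- xC[bp$gmap] + gx
    Cs <- bp$A0
    Cs@x <- xC
    rhs <- e11 * bp$v11 + e22 * bp$v22 + e12 * bp$vsym
    yWy <- e11 * bp$y11 + e22 * bp$y22 + e12 * bp$ysym
    res <- tryCatch(suppressWarnings({
        ch <- Matrix::update(bp$ch0, Cs)
        list(ld = 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus),
             sol = as.numeric(Matrix::solve(ch, rhs, system = "A")))
    }), error = function(e) NULL)
    if (is.null(res) || !all(is.finite(res$sol))) return(1e10)
    yPy <- yWy - sum(rhs * res$sol)
    logR <- bp$nPlot * log(dSE)
    logG <- bp$g * log(dSG) + sum(rep(log(vr), bp$r))
    logR + logG + res$ld + yPy
}

.bivFit <- function(bp, zeroCov = FALSE, computeSE = TRUE) {
    v1 <- var(bp$y[bp$trait == 1L]); v2 <- var(bp$y[bp$trait == 2L])
    mk <- function(f1, f2) {
        if (zeroCov)
            c(0.5 * log(f1 * v1), 0.5 * log(f1 * v2),
              log(0.05 * v1) , log(0.05 * v2),
              0.5 * log(f2 * v1), 0.5 * log(f2 * v2))
        else
            c(0.5 * log(f1 * v1), 0, 0.5 * log(f1 * v2),
              log(0.05 * v1), log(0.05 * v2),
              0.5 * log(f2 * v1), 0, 0.5 * log(f2 * v2))
    }
    starts <- list(mk(0.5, 0.5), mk(0.8, 0.2), mk(0.2, 0.8))
    best <- NULL; conv <- FALSE
    for (s0 in starts) {
        o <- tryCatch(optim(s0, .bivNeg2REML, bp = bp, zeroCov = zeroCov,
                            method = "BFGS", control = list(maxit = 500)),
                      error = function(e) NULL)
        if (is.null(o)) next
        if (is.null(best) || o$value < best$value - 1e-9) {
            best <- o; conv <- o$convergence == 0L
        }
    }
    if (is.null(best)) stop("bivariate REML optimization failed")
    par <- best$par
    full <- if (zeroCov)
        c(par[1L], 0, par[2L], par[3L], par[4L], par[5L], 0, par[6L])
    else par
    SG <- .lchol2(full[1:3]); SE <- .lchol2(full[6:8])
    vr <- exp(full[4:5])
    covGse <- NA_real_
    if (!zeroCov && computeSE) {
        H <- .numHessian(function(p) .bivNeg2REML(p, bp), par)
        Vp <- tryCatch(2 * solve(H), error = function(e) NULL)
        if (!is.null(Vp)) {
            gr <- .numGrad(function(p) {
                exp(p[1L]) * p[2L]        # covG = L11 * L21
            }, par)
            v <- drop(t(gr) %*% Vp %*% gr)
            if (is.finite(v) && v > 0) covGse <- sqrt(v)
        }
    }
    list(SG = SG, SE = SE, repVar = vr, neg2REML = best$value,
         logLik = -0.5 * best$value, converged = conv, covGse = covGse)
}

.numGrad <- function(f, x, h = 1e-5) {
    g <- numeric(length(x))
    for (i in seq_along(x)) {
        hp <- xm <- xp <- x
        xp[i] <- x[i] + h; xm[i] <- x[i] - h
        g[i] <- (f(xp) - f(xm)) / (2 * h)
    }
    g
}

.numHessian <- function(f, x, h = 1e-4) {
    m <- length(x)
    H <- matrix(NA_real_, m, m)
    f0 <- f(x)
    for (a in seq_len(m)) for (b in a:m) {
        if (a == b) {
            xp <- x; xp[a] <- x[a] + h
            xm <- x; xm[a] <- x[a] - h
            H[a, a] <- (f(xp) - 2 * f0 + f(xm)) / h^2
        } else {
            s <- function(da, db) { z <- x; z[a] <- z[a] + da; z[b] <- z[b] + db; f(z) }
            H[a, b] <- H[b, a] <- (s(h, h) - s(h, -h) - s(-h, h) + s(-h, -h)) / (4 * h^2)
        }
    }
    H
}
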