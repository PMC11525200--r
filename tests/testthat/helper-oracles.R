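# Independent oracles used across the suite. These deliberately share no
# code with the package: plain-R reimplementations against which the
# package's (sometimes compiled) paths are checked.

# single-clone critical birth-death Gillespie, pure R
r_gillespie_bd <- function(n0, kappa, tmax) {
    n <- n0
    t <- 0
    repeat {
        if (n == 0) return(0L)
        t <- t + rexp(1, rate = 2 * kappa * n)
        if (t > tmax) return(n)
        n <- n + sample(c(1L, -1L), 1)
    }
}

# recursive flood fill over same-color labeled sites of a matrix
flood_fill_components <- function(mat, connectivity = 4) {
    nr <- nrow(mat); nc <- ncol(mat)
    seen <- matrix(FALSE, nr, nc)
    nb <- if (connectivity == 4) {
        rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
    } else {
        as.matrix(expand.grid(-1:1, -1:1))[-5, ]
    }
    comps <- list()
    for (j in seq_len(nc)) for (i in seq_len(nr)) {
        if (mat[i, j] == 0 || seen[i, j]) next
        col <- mat[i, j]
        stack <- list(c(i, j))
        seen[i, j] <- TRUE
        size <- 0L
        while (length(stack)) {
            p <- stack[[length(stack)]]
            stack[[length(stack)]] <- NULL
            size <- size + 1L
            for (k in seq_len(nrow(nb))) {
                q <- p + nb[k, ]
                if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
                    !seen[q[1], q[2]] && mat[q[1], q[2]] == col) {
                    seen[q[1], q[2]] <- TRUE
                    stack[[length(stack) + 1L]] <- q
                }
            }
        }
        comps[[length(comps) + 1L]] <- c(color = col, size = size)
    }
    if (!length(comps)) return(data.frame(color = integer(), size = integer()))
    out <- as.data.frame(do.call(rbind, comps))
    out[order(out$color, out$size), , drop = FALSE]
}

# hand-written decision table for the six trajectory classes, organised
# differently from the package's rule cascade
oracle_class <- function(a1, a2, a3) {
    if (a3 == 0) {
        if (a2 == 0) return("Decay1")
        return("Decay2")
    }
    strictly_down <- a1 > a2 && a2 > a3
    up_then_down <- a1 < a2 && a2 > a3
    strictly_up <- a1 < a2 && a2 < a3
    if (strictly_down) return("Decay3")
    if (up_then_down) return("Biphasic")
    if (strictly_up) return("Growing")
    "Steady"
}

# two-sided exact signed-rank p by enumerating all sign assignments
enumerate_signed_rank_p <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.vector(signs %*% r)
    mu <- n * (n + 1) / 4
    mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12)
}

# least-squares slope via explicit normal equations
normal_eq_slope <- function(x, y) {
    X <- cbind(1, x)
    solve(t(X) %*% X, t(X) %*% y)[2]
}

make_traj <- function(id, areas, weeks = 4:19, culture = "c1") {
    names(areas) <- as.character(weeks)
    SCATrajectory(scaId = id, cultureId = culture, areas = areas)
}

# trajectory with given window means: constant within each window
traj_from_windows <- function(w, id = "t1") {
    areas <- c(rep(w[1], 5), NA, rep(w[2], 4), NA, rep(w[3], 5))
    names(areas) <- as.character(4:19)
    areas <- areas[!is.na(areas)]
    SCATrajectory(scaId = id, cultureId = "c1", areas = areas)
}
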