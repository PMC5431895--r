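## Independent oracles and small fixtures used across the suite. Everything
## here is deliberately written with different algorithms/code paths than the
## package implementation it checks.

## Tarjan's strongly connected components, iterative, on an adjacency matrix.
tarjan_scc <- function(adj) {
  n <- nrow(adj)
  index <- rep(NA_integer_, n); low <- rep(NA_integer_, n)
  onstack <- rep(FALSE, n); stack <- integer(); counter <- 0L
  comps <- list()
  for (root in seq_len(n)) {
    if (!is.na(index[root])) next
    ## explicit DFS stack: (node, next-neighbor-pointer)
    dfs <- list(list(v = root, i = 0L))
    while (length(dfs)) {
      fr <- dfs[[length(dfs)]]
      v <- fr$v
      if (fr$i == 0L) {
        counter <- counter + 1L
        index[v] <- low[v] <- counter
        stack <- c(stack, v); onstack[v] <- TRUE
      }
      nbrs <- which(adj[v, ] > 0)
      advanced <- FALSE
      while (fr$i < length(nbrs)) {
        fr$i <- fr$i + 1L
        w <- nbrs[fr$i]
        if (is.na(index[w])) {
          dfs[[length(dfs)]] <- fr
          dfs[[length(dfs) + 1L]] <- list(v = w, i = 0L)
          advanced <- TRUE
          break
        } else if (onstack[w]) {
          low[v] <- min(low[v], index[w])
        }
      }
      if (advanced) next
      dfs[[length(dfs)]] <- NULL
      if (low[v] == index[v]) {
        pos <- max(which(stack == v))
        comp <- stack[pos:length(stack)]
        stack <- stack[seq_len(pos - 1L)]
        onstack[comp] <- FALSE
        comps[[length(comps) + 1L]] <- sort(comp)
      }
      if (length(dfs)) {
        p <- dfs[[length(dfs)]]$v
        low[p] <- min(low[p], low[v])
      }
    }
  }
  comps
}

## Textbook dihedral via explicit vector algebra (acos branch + sign).
dihedral_oracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(max(-1, min(1, cosang)))
  if (sum(n1 * b3) < 0) ang <- -ang
  ang
}

## Nested grid search over Euler angles for the minimal RMSD under rotation
## (translation removed by centering) - independent of the Kabsch route.
grid_rmsd_oracle <- function(a, b) {
  a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
  rot <- function(al, be, ga) {
    Rz1 <- matrix(c(cos(al), -sin(al), 0, sin(al), cos(al), 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cos(be), 0, sin(be), 0, 1, 0, -sin(be), 0, cos(be)), 3, byrow = TRUE)
    Rz2 <- matrix(c(cos(ga), -sin(ga), 0, sin(ga), cos(ga), 0, 0, 0, 1), 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  rmsd_at <- function(al, be, ga) sqrt(mean(rowSums((b %*% t(rot(al, be, ga)) - a)^2)))
  ctr <- c(0, 0, 0); width <- pi
  best <- Inf
  for (lvl in 1:6) {
    gr <- seq(-width, width, length.out = 11)
    vals <- expand.grid(al = ctr[1] + gr, be = ctr[2] + gr / 2, ga = ctr[3] + gr)
    r <- mapply(rmsd_at, vals$al, vals$be, vals$ga)
    i <- which.min(r)
    best <- r[i]
    ctr <- c(vals$al[i], vals$be[i], vals$ga[i])
    width <- width / 5
  }
  best
}

## Tiny topology builder for geometric featurizer tests: explicit atoms with
## given roles and coordinates (one frame, or a frames x atoms x 3 array).
toy_system <- function(roles, coords, box = c(10, 10, 10), frame_interval = 1) {
  n <- length(roles)
  elety <- ifelse(roles == "alpha_carbon", "CA",
           ifelse(roles == "water_oxygen", "O",
           ifelse(roles == "lipid_phosphorus", "P",
           ifelse(roles == "zinc", "ZN", "X"))))
  topo <- mem_topology(data.frame(
    eleno = seq_len(n), elety = elety,
    resid = ifelse(roles == "water_oxygen", "HOH",
            ifelse(roles == "lipid_phosphorus", "LIP", "ALA")),
    resno = seq_len(n), role = roles, stringsAsFactors = FALSE))
  if (length(dim(coords)) == 2) {
    xyz <- array(coords, c(1, n, 3))
  } else xyz <- coords
  list(topo = topo, traj = mem_trajectory(xyz, box, frame_interval, topo))
}

## Random rigid transform of a frames x atoms x 3 array.
apply_rigid <- function(xyz, R, t) {
  out <- xyz
  for (f in seq_len(dim(xyz)[1])) {
    m <- xyz[f, , , drop = FALSE]; dim(m) <- dim(xyz)[2:3]
    out[f, , ] <- m %*% t(R) + matrix(t, dim(xyz)[2], 3, byrow = TRUE)
  }
  out
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

## Small two-well generator config for fast tests (coarser statistics than
## the package defaults, same physics).
small_two_well <- function(n_trajectories = 30L, frames_per_trajectory = 120L, ...) {
  config_two_well(n_trajectories = n_trajectories,
                  frames_per_trajectory = frames_per_trajectory, ...)
}

## Feature matrices straight from CV trajectories (d, theta as 2 features).
cv_features <- function(cvs) {
  lapply(cvs$trajectories, function(m)
    memsm:::feature_matrix(m[, 1:2, drop = FALSE], c("d", "theta"),
                           cvs$frame_interval))
}

## Reference pipeline from CV trajectories to an MSM, used by several tests.
cv_msm_fit <- function(cvs, k = 20, tica_lag = 2, g = 1e-6, tau = 4.5,
                       seed = 5) {
  feats <- cv_features(cvs)
  tica <- fit_tica(feats, lag = tica_lag, g = g, n_components = 2)
  tics <- tica_transform(tica, feats)
  cm <- fit_minibatch_kmeans(tics, k = k, seed = seed)
  states <- assign_states(cm, tics)
  msm <- build_msm(states, tau = tau, frame_interval = cvs$frame_interval, k = k)
  list(tica = tica, tics = tics, cluster = cm, states = states, msm = msm)
}

## Independent oracle: accumulate the lagged-pair statistics by explicit
## loops and solve the generalized problem with a plain dense solver.
tica_oracle <- function(features, lag_frames, g) {
  p <- ncol(features[[1]])
  xs <- NULL; pairs0 <- NULL; pairst <- NULL
  for (X in features) {
    if (nrow(X) <= lag_frames) next
    for (t in 1:(nrow(X) - lag_frames)) {
      pairs0 <- rbind(pairs0, X[t, ])
      pairst <- rbind(pairst, X[t + lag_frames, ])
    }
  }
  mu <- colMeans(rbind(pairs0, pairst))
  A0 <- sweep(pairs0, 2, mu); At <- sweep(pairst, 2, mu)
  n <- nrow(A0)
  C00 <- (crossprod(A0) + crossprod(At)) / (2 * n)
  C0t <- crossprod(A0, At) / n
  Cbar <- (C0t + t(C0t)) / 2
  B <- C00 + g * diag(p)
  e <- eigen(solve(B, Cbar))
  ord <- order(Re(e$values), decreasing = TRUE)
  list(values = Re(e$values)[ord], vectors = Re(e$vectors)[, ord, drop = FALSE])
}


## Independent oracle for the self-score identity: accumulate the train
## matrices with table() and solve the generalized problem densely.
train_eigensum_oracle <- function(states, lag_frames, k, m) {
  C <- matrix(0, k, k)
  for (s in states) {
    i <- s[1:(length(s) - lag_frames)]; j <- s[(lag_frames + 1):length(s)]
    for (t in seq_along(i)) C[i[t], j[t]] <- C[i[t], j[t]] + 1
  }
  active <- suppressMessages(largest_connected_set(C))
  Ca <- C[active, active, drop = FALSE]
  N <- sum(Ca)
  Cbar <- (Ca + t(Ca)) / (2 * N)
  S <- diag((rowSums(Ca) + colSums(Ca)) / (2 * N))
  ev <- eigen(solve(S, Cbar))$values
  sum(sort(Re(ev), decreasing = TRUE)[seq_len(min(m, length(ev)))])
}

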