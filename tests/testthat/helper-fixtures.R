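# shared fixtures and small independent oracles

# tiny aligned two-view mvdata with a binary outcome
make_tiny_mvdata <- function(n = 20, p1 = 4, p2 = 3, seed = 1) {
  set.seed(seed)
  ids <- paste0("s", seq_len(n))
  X1 <- matrix(rnorm(n * p1), n, dimnames = list(ids, paste0("a", seq_len(p1))))
  X2 <- matrix(rnorm(n * p2), n, dimnames = list(ids, paste0("b", seq_len(p2))))
  y <- rep(c(0, 1), length.out = n)
  multiview_data(list(V1 = X1, V2 = X2), outcome = mv_outcome(y, kind = "binary"))
}

# support-recovery F1
f1_support <- function(selected, truth) {
  tp <- length(intersect(selected, truth))
  if (length(selected) + length(truth) == 0) return(NA_real_)
  2 * tp / (length(selected) + length(truth))
}

# write a matrix as the CLI's CSV layout (id column + header)
write_view_csv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}

# solve the SELP subproblem with scipy.optimize.linprog (independent oracle);
# returns a list of solutions, or NULL if python is unavailable
selp_lp_oracle <- function(instances) {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "") return(NULL)
  script <- '
import json, sys
import numpy as np
from scipy.optimize import linprog
inst = json.load(open(sys.argv[1]))
out = []
for ins in inst:
    c = np.array(ins["c"]); rho = ins["rho"]; tau = ins["tau"]
    p = len(c)
    obj = np.ones(2 * p)
    A = np.vstack([np.hstack([rho * np.eye(p), -rho * np.eye(p)]),
                   np.hstack([-rho * np.eye(p), rho * np.eye(p)])])
    b = np.concatenate([c + tau, tau - c])
    r = linprog(obj, A_ub=A, b_ub=b, bounds=[(0, None)] * 2 * p, method="highs")
    u = r.x[:p] - r.x[p:]
    out.append(list(u))
json.dump(out, open(sys.argv[2], "w"))
'
  sf <- tempfile(fileext = ".py"); writeLines(script, sf)
  inf <- tempfile(fileext = ".json"); outf <- tempfile(fileext = ".json")
  jsonlite::write_json(instances, inf, auto_unbox = TRUE, digits = NA)
  status <- system2(py, c(sf, inf, outf), stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(outf)) return(NULL)
  jsonlite::read_json(outf, simplifyVector = TRUE)
}

# Moore-Penrose pseudo-inverse via SVD (q x p for a p x q input)
MASS_ginv <- function(G) {
  sv <- svd(G)
  pos <- sv$d > 1e-10
  sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

# evaluate code under a temporary seed, restoring the RNG state
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# mean silhouette width for a 2-D embedding with known groups (hand-rolled)
mean_silhouette <- function(xy, groups) {
  d <- as.matrix(dist(xy))
  groups <- as.character(groups)
  mean(vapply(seq_len(nrow(xy)), function(i) {
    own <- groups == groups[i]
    a <- mean(d[i, own & seq_len(nrow(xy)) != i])
    b <- min(vapply(setdiff(unique(groups), groups[i]),
                    function(g) mean(d[i, groups == g]), 0))
    (b - a) / max(a, b)
  }, 0))
}
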