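## Linear / mixed-integer programming back ends.
##
## All optimisation models in the package (MDF linear program, pathway-search
## MILP, FBA) are assembled in R in one standard form,
##
##     min/max  c'x   s.t.  clb <= A x <= cub,  vlb <= x <= vub,
##              x[integrality == 1] integer,
##
## and handed to one of two engines:
##   * "highs"  - HiGHS through scipy.optimize.milp in a `python` subprocess
##                (the only MILP-capable solver in the stack);
##   * "simplex" - the package's own two-phase dense simplex (simplex.R),
##                LP only.  Used as the independent engine for oracle
##                cross-checks so that an implementation and its oracle
##                never share a solver.

.LP_INF <- 1e30

#' Assemble a standard-form LP/MILP problem
#'
#' @param obj numeric objective coefficients.
#' @param A constraint matrix (dense or any Matrix sparse class).
#' @param clb,cub constraint lower/upper bounds (`-Inf`/`Inf` allowed).
#' @param vlb,vub variable bounds.
#' @param integrality integer vector, 1 = integer-constrained variable.
#' @param sense `"max"` or `"min"`.
#' @return an object of class `lpProblem`.
#' @keywords internal
lpProblem <- function(obj, A, clb, cub, vlb, vub,
                      integrality = rep(0L, length(obj)),
                      sense = c("min", "max")) {
  sense <- match.arg(sense)
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"),
                   "TsparseMatrix")
  n <- length(obj)
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(clb) == m, length(cub) == m,
            length(vlb) == n, length(vub) == n, length(integrality) == n)
  structure(list(obj = obj, A = A, clb = clb, cub = cub,
                 vlb = vlb, vub = vub,
                 integrality = as.integer(integrality), sense = sense),
            class = "lpProblem")
}

.pythonBinary <- function() {
  py <- getOption("latentpath.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  py
}

#' Is the MILP engine available?
#' @return `TRUE` if a python interpreter with scipy is on the PATH.
#' @export
hasMilpSolver <- function() {
  nzchar(.pythonBinary())
}

.capBounds <- function(v) {
  v[v > .LP_INF] <- .LP_INF
  v[v < -.LP_INF] <- -.LP_INF
  v
}

## Solve a list of lpProblem objects in one python call (HiGHS).
.solveHighsBatch <- function(problems) {
  py <- .pythonBinary()
  if (!nzchar(py)) {
    stop("no MILP solver available: `python` (with scipy) not found on PATH",
         call. = FALSE)
  }
  script <- system.file("python", "solve_milp.py", package = "latentpath",
                        mustWork = TRUE)
  payload <- lapply(problems, function(p) {
    list(sense = p$sense,
         c = p$obj,
         A = list(i = p$A@i + 1L, j = p$A@j + 1L, x = p$A@x,
                  nrow = nrow(p$A), ncol = ncol(p$A)),
         clb = .capBounds(p$clb), cub = .capBounds(p$cub),
         vlb = .capBounds(p$vlb), vub = .capBounds(p$vub),
         integrality = p$integrality)
  })
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- system2(py, c(shQuote(script), shQuote(fin), shQuote(fout)),
                    stdout = FALSE, stderr = "")
  if (status != 0L || !file.exists(fout)) {
    stop("MILP back end failed (python exit status ", status, ")",
         call. = FALSE)
  }
  res <- jsonlite::read_json(fout, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(res, function(r) {
    list(status = r$status,
         objective = if (is.null(r$objective)) NA_real_ else as.numeric(r$objective),
         x = if (is.null(r$x)) NULL else as.numeric(r$x),
         message = r$message)
  })
}

#' Solve a standard-form LP/MILP
#'
#' @param problem an [lpProblem()].
#' @param engine `"highs"` (default; MILP-capable, via scipy) or
#'   `"simplex"` (the package's own pure-R two-phase simplex, LP only;
#'   used for solver-independent cross-checks).
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"error"`),
#'   `objective` and the primal solution `x`.
#' @keywords internal
solveLp <- function(problem, engine = c("highs", "simplex")) {
  engine <- match.arg(engine)
  if (engine == "simplex") {
    .solveSimplexR(problem)
  } else {
    .solveHighsBatch(list(problem))[[1L]]
  }
}
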