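## Local strain energy of the variable moiety: single-point energy of the
## bound (crystallographic) conformation minus the energy of the locally
## optimized isolated conformation, in kcal/mol. The energy itself comes
## from a pluggable backend; a deterministic analytic reference backend
## (harmonic bonds/angles plus pairwise repulsion) ships with the package.

#' Construct an isolated molecule
#'
#' @param elements Character vector of element symbols.
#' @param xyz n x 3 matrix of Cartesian coordinates, Angstrom.
#' @param charge Formal charge (informational; passed to backends).
#' @return An object of class \code{molecule}.
#' @export
molecule <- function(elements, xyz, charge = 0) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != length(elements) || ncol(xyz) != 3L) {
    stop("xyz must be an n x 3 matrix matching the element list")
  }
  dimnames(xyz) <- NULL
  structure(list(elements = elements, xyz = xyz, charge = charge),
            class = "molecule")
}

#' Extract the variable moiety of a mode as an isolated molecule
#'
#' The moiety is scored in isolation, exactly as the strain definition
#' prescribes; surrounding atoms are never sent to the backend. Hydrogens
#' belong to the moiety (they define the mode), so build the selection with
#' \code{exclude_hydrogens = FALSE} for strain scoring.
#'
#' @param s An [xtal_structure()].
#' @param sel An [atom_selection()].
#' @param charge Formal charge of the moiety.
#' @return A [molecule()].
#' @export
extract_moiety <- function(s, sel, charge = 0) {
  a <- select_atoms(s, sel)
  molecule(a$element, as.matrix(a[, c("x", "y", "z")]), charge)
}

new_energy_backend <- function(single_point, optimize, name,
                               settings = list()) {
  structure(list(single_point = single_point, optimize = optimize,
                 name = name, settings = settings),
            class = "energy_backend")
}

#' @export
print.energy_backend <- function(x, ...) {
  cat(sprintf("<energy_backend> %s\n", x$name))
  invisible(x)
}

# Energy (and analytic gradient) of the reference force field.
# params: list(bonds = df(i, j, k_bond, r0), angles = df(i, j, k, k_theta,
# theta0) with j the apex, repulsion_a, e0).
reference_energy <- function(xyz, params, gradient = FALSE) {
  e <- params$e0
  g <- if (gradient) matrix(0, nrow(xyz), 3) else NULL
  bonds <- params$bonds
  if (!is.null(bonds) && nrow(bonds)) {
    for (q in seq_len(nrow(bonds))) {
      i <- bonds$i[q]; j <- bonds$j[q]
      dv <- xyz[i, ] - xyz[j, ]
      r <- sqrt(sum(dv^2))
      dr <- r - bonds$r0[q]
      e <- e + 0.5 * bonds$k_bond[q] * dr^2
      if (gradient) {
        f <- bonds$k_bond[q] * dr * dv / r
        g[i, ] <- g[i, ] + f
        g[j, ] <- g[j, ] - f
      }
    }
  }
  angles <- params$angles
  if (!is.null(angles) && nrow(angles)) {
    for (q in seq_len(nrow(angles))) {
      i <- angles$i[q]; j <- angles$j[q]; k <- angles$k[q]
      u <- xyz[i, ] - xyz[j, ]; v <- xyz[k, ] - xyz[j, ]
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      ct <- max(-1, min(1, sum(u * v) / (nu * nv)))
      th <- acos(ct)
      dth <- th - angles$theta0[q]
      e <- e + 0.5 * angles$k_theta[q] * dth^2
      if (gradient) {
        st <- sqrt(max(1e-12, 1 - ct^2))
        gi <- (ct * (u / nu) - v / nv) / (nu * st)
        gk <- (ct * (v / nv) - u / nu) / (nv * st)
        gj <- -(gi + gk)
        cf <- angles$k_theta[q] * dth
        g[i, ] <- g[i, ] + cf * gi
        g[j, ] <- g[j, ] + cf * gj
        g[k, ] <- g[k, ] + cf * gk
      }
    }
  }
  if (!is.null(params$repulsion_a) && params$repulsion_a > 0) {
    n <- nrow(xyz)
    excluded <- matrix(FALSE, n, n)
    if (!is.null(bonds) && nrow(bonds)) {
      excluded[cbind(bonds$i, bonds$j)] <- TRUE
      excluded[cbind(bonds$j, bonds$i)] <- TRUE
    }
    if (!is.null(angles) && nrow(angles)) {     # 1-3 pairs excluded too
      excluded[cbind(angles$i, angles$k)] <- TRUE
      excluded[cbind(angles$k, angles$i)] <- TRUE
    }
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          if (excluded[i, j]) next
          dv <- xyz[i, ] - xyz[j, ]
          r2 <- sum(dv^2)
          e <- e + params$repulsion_a / r2^6
          if (gradient) {
            f <- -12 * params$repulsion_a / r2^7 * dv
            g[i, ] <- g[i, ] + f
            g[j, ] <- g[j, ] - f
          }
        }
      }
    }
  }
  if (gradient) list(energy = e, gradient = g) else e
}

check_ff_params <- function(mol, params) {
  n <- nrow(mol$xyz)
  chk <- function(df, cols, what) {
    if (is.null(df) || !nrow(df)) return(invisible())
    idx <- unlist(df[cols])
    if (any(idx < 1 | idx > n)) {
      stop("parameter table references atom outside the molecule in a ",
           what, " term")
    }
  }
  chk(params$bonds, c("i", "j"), "bond")
  chk(params$angles, c("i", "j", "k"), "angle")
  if ((is.null(params$bonds) || !nrow(params$bonds)) && n > 1) {
    stop("missing parameter: no bond terms cover the molecule")
  }
}

#' Analytic reference energy backend
#'
#' Deterministic backend for testing and synthetic ensembles: harmonic bond
#' and angle terms plus an optional r^-12 repulsion between non-bonded
#' pairs, with analytic gradients, in kcal/mol and Angstrom. Local
#' optimization is BFGS descent from the input geometry, accepted when the
#' gradient norm falls below \code{grad_tol}; the returned optimized energy
#' is never above the single-point energy (the start point is always a
#' candidate).
#'
#' @param bonds data.frame(i, j, k_bond, r0): atom indices, force constant
#'   (kcal/mol/A^2), equilibrium length (A).
#' @param angles Optional data.frame(i, j, k, k_theta, theta0): indices with
#'   j the apex, force constant (kcal/mol/rad^2), equilibrium angle (rad).
#' @param repulsion_a Coefficient of the pairwise r^-12 repulsion
#'   (kcal/mol A^12); 0 disables it.
#' @param e0 Constant energy offset, kcal/mol.
#' @param grad_tol Gradient-norm convergence threshold, kcal/mol/A.
#' @param max_iter Iteration cap for the optimizer.
#' @return An \code{energy_backend}.
#' @export
reference_backend <- function(bonds, angles = NULL, repulsion_a = 0, e0 = 0,
                              grad_tol = 1e-6, max_iter = 2000L) {
  if (!is.data.frame(bonds) ||
      !all(c("i", "j", "k_bond", "r0") %in% names(bonds))) {
    stop("bonds must be a data.frame with columns i, j, k_bond, r0")
  }
  if (!is.null(angles) &&
      !all(c("i", "j", "k", "k_theta", "theta0") %in% names(angles))) {
    stop("angles must have columns i, j, k, k_theta, theta0")
  }
  params <- list(bonds = bonds, angles = angles,
                 repulsion_a = repulsion_a, e0 = e0)
  single_point <- function(mol) {
    check_ff_params(mol, params)
    reference_energy(mol$xyz, params)
  }
  optimize <- function(mol) {
    check_ff_params(mol, params)
    n <- nrow(mol$xyz)
    fn <- function(p) reference_energy(matrix(p, n, 3), params)
    gr <- function(p) as.vector(reference_energy(matrix(p, n, 3), params,
                                                 gradient = TRUE)$gradient)
    res <- stats::optim(as.vector(mol$xyz), fn, gr, method = "BFGS",
                        control = list(maxit = max_iter, reltol = 1e-14))
    # polish until the gradient norm meets the contract
    for (rep in 1:5) {
      if (sqrt(sum(gr(res$par)^2)) <= grad_tol) break
      res <- stats::optim(res$par, fn, gr, method = "BFGS",
                          control = list(maxit = max_iter, reltol = 1e-16))
    }
    gnorm <- sqrt(sum(gr(res$par)^2))
    if (gnorm > grad_tol) {
      stop(sprintf("reference backend failed to converge: |grad| = %.2e", gnorm))
    }
    e_start <- fn(as.vector(mol$xyz))
    if (res$value > e_start) {            # descent contract: start is a candidate
      res$par <- as.vector(mol$xyz)
      res$value <- e_start
    }
    list(energy = res$value, xyz = matrix(res$par, n, 3))
  }
  new_energy_backend(single_point, optimize, "reference-harmonic",
                     list(grad_tol = grad_tol, repulsion_a = repulsion_a))
}

#' Wrap an external energy program as a backend
#'
#' The command template must contain the placeholders \code{{input}} and
#' \code{{output}}. The molecule is written to \code{{input}} in XYZ format
#' (count line, comment line with the formal charge, then
#' "element x y z" rows); the program must write to \code{{output}} two
#' lines, \code{single_point <kcal/mol>} and \code{optimized <kcal/mol>}, or
#' a custom \code{parser(output_path)} returning that pair must be given.
#'
#' @param command_template Shell command with \code{{input}}/\code{{output}}.
#' @param parser Optional function(path) returning
#'   list(single_point=, optimized=).
#' @param workdir Directory for run files (kept for provenance).
#' @return An \code{energy_backend}.
#' @export
external_backend <- function(command_template, parser = NULL,
                             workdir = tempdir()) {
  if (!grepl("{input}", command_template, fixed = TRUE) ||
      !grepl("{output}", command_template, fixed = TRUE)) {
    stop("command template must contain both {input} and {output} placeholders")
  }
  if (is.null(parser)) {
    parser <- function(path) {
      lines <- readLines(path, warn = FALSE)
      getnum <- function(tag) {
        ln <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)
        if (!length(ln)) return(NA_real_)
        as.numeric(strsplit(trimws(ln[1]), "\\s+")[[1]][2])
      }
      list(single_point = getnum("single_point"), optimized = getnum("optimized"))
    }
  }
  run <- function(mol) {
    stamp <- format(Sys.time(), "%H%M%OS3")
    inp <- file.path(workdir, paste0("mol-", stamp, ".xyz"))
    outp <- file.path(workdir, paste0("mol-", stamp, ".out"))
    writeLines(c(as.character(nrow(mol$xyz)),
                 paste("charge", mol$charge),
                 sprintf("%-2s %14.8f %14.8f %14.8f", mol$elements,
                         mol$xyz[, 1], mol$xyz[, 2], mol$xyz[, 3])), inp)
    cmd <- gsub("{output}", outp,
                gsub("{input}", inp, command_template, fixed = TRUE),
                fixed = TRUE)
    status <- system(cmd)
    if (status != 0) {
      stop("external energy backend exited with status ", status, ": ", cmd)
    }
    if (!file.exists(outp)) stop("external backend wrote no output file: ", outp)
    res <- parser(outp)
    if (!is.finite(res$single_point) || !is.finite(res$optimized)) {
      stop("unparseable external backend output in ", outp, ": ",
           paste(readLines(outp, warn = FALSE), collapse = " | "))
    }
    res
  }
  new_energy_backend(
    single_point = function(mol) run(mol)$single_point,
    optimize = function(mol) {
      res <- run(mol)
      if (res$optimized > res$single_point + 1e-9) {
        stop(sprintf(
          "backend contract violated: optimized energy %.6g above single-point %.6g",
          res$optimized, res$single_point))
      }
      list(energy = res$optimized, xyz = mol$xyz)
    },
    name = paste("external:", command_template))
}

#' Strain energy of a moiety
#'
#' strain = E_single_point - E_optimized, both from the same backend on the
#' isolated moiety. Nonnegative by the backend contract (tiny negative
#' optimizer round-off below 1e-9 kcal/mol is clipped to zero).
#'
#' @param mol A [molecule()] (the mode's moiety, protons included).
#' @param backend An \code{energy_backend}.
#' @return An object of class \code{strain_result}: e_single_point,
#'   e_optimized, strain (kcal/mol), backend name.
#' @export
strain_energy <- function(mol, backend) {
  stopifnot(inherits(mol, "molecule"), inherits(backend, "energy_backend"))
  e_sp <- backend$single_point(mol)
  opt <- backend$optimize(mol)
  strain <- e_sp - opt$energy
  if (strain < -1e-9) {
    stop(sprintf("backend contract violated: strain = %.6g < 0", strain))
  }
  strain <- max(0, strain)
  structure(list(e_single_point = e_sp, e_optimized = opt$energy,
                 strain = strain, backend = backend$name),
            class = "strain_result")
}

#' @export
print.strain_result <- function(x, ...) {
  cat(sprintf("<strain_result> SE = %.4f kcal/mol (SP %.4f, opt %.4f; %s)\n",
              x$strain, x$e_single_point, x$e_optimized, x$backend))
  invisible(x)
}
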