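# Readers and writers: two-column XVG-tolerant tables, plain-text
# trajectories, GRO coordinates, TOML-style parameter configs, and
# GROMACS-dialect topology-include snippets.

#' Read a whitespace-delimited numeric table
#'
#' Reads two- or three-column numeric tables, skipping `#` comment lines and
#' tolerating XVG `@` metadata lines.
#'
#' @param path File path.
#' @return Data frame with columns `x`, `y` (and `err` if a third column is
#'   present).
#' @export
read_xy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*([#@]|$)", lines)]
  if (length(lines) == 0L) stop("no data rows in ", path)
  m <- utils::read.table(text = lines, header = FALSE)
  if (ncol(m) < 2L) stop("expected at least two numeric columns in ", path)
  out <- data.frame(x = m[[1]], y = m[[2]])
  if (ncol(m) >= 3L) out$err <- m[[3]]
  out
}

#' Write a whitespace-delimited numeric table
#'
#' @param path Output path.
#' @param x,y Numeric vectors (or pass a two-column data frame as `x`).
#' @param header Comment lines to prepend (without the leading `#`).
#' @param err Optional third column.
#' @export
write_xy <- function(path, x, y = NULL, header = character(), err = NULL) {
  if (is.data.frame(x)) {
    df <- x
    if (ncol(df) < 2L) stop("data frame must have at least two columns")
    x <- df[[1]]; y <- df[[2]]
    if (is.null(err) && ncol(df) >= 3L) err <- df[[3]]
  }
  stopifnot(length(x) == length(y))
  con <- file(path, "w"); on.exit(close(con))
  for (h in header) writeLines(paste("#", h), con)
  body <- if (is.null(err)) sprintf("%.8g %.8g", x, y)
          else sprintf("%.8g %.8g %.8g", x, y, err)
  writeLines(body, con)
  invisible(path)
}

#' Write a trajectory as plain XYZ-with-box text
#'
#' Format: a `#`-comment header, then per frame one line
#' `frame <time_ps> <bx> <by> <bz>` followed by one `<role> <x> <y> <z>`
#' line per atom (nm), in constant atom order.
#'
#' @param path Output path.
#' @param traj A [trajectory].
#' @export
write_xyz_traj <- function(path, traj) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# plain XYZ-with-box trajectory: frame t bx by bz / role x y z", con)
  roles <- names(traj$coords)
  for (t in seq_along(traj$times)) {
    writeLines(sprintf("frame %.8g %.8g %.8g %.8g", traj$times[t],
                       traj$box[t, 1], traj$box[t, 2], traj$box[t, 3]), con)
    for (role in roles) {
      X <- traj$coords[[role]]
      for (i in seq_len(dim(X)[2]))
        writeLines(sprintf("%s %.8g %.8g %.8g", role,
                           X[t, i, 1], X[t, i, 2], X[t, i, 3]), con)
    }
  }
  invisible(path)
}

#' Read a plain XYZ-with-box trajectory
#'
#' Inverse of [write_xyz_traj].
#'
#' @param path File path.
#' @return A [trajectory].
#' @export
read_xyz_traj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  is_frame <- startsWith(lines, "frame ")
  if (!any(is_frame)) stop("no 'frame' records in ", path)
  starts <- which(is_frame)
  nf <- length(starts)
  ends <- c(starts[-1] - 1L, length(lines))
  natoms <- ends[1] - starts[1]
  hdr <- do.call(rbind, strsplit(lines[starts], "\\s+"))
  times <- as.numeric(hdr[, 2])
  box <- matrix(as.numeric(hdr[, 3:5]), nf, 3)
  atom_lines <- lines[-starts]
  parts <- do.call(rbind, strsplit(atom_lines, "\\s+"))
  roles_per_frame <- parts[seq_len(natoms), 1]
  xyz <- matrix(as.numeric(parts[, 2:4]), ncol = 3)
  coords <- list()
  for (role in unique(roles_per_frame)) {
    sel <- which(roles_per_frame == role)
    na_ <- length(sel)
    A <- array(NA_real_, c(nf, na_, 3))
    for (t in seq_len(nf)) {
      rows <- (t - 1L) * natoms + sel
      A[t, , ] <- xyz[rows, , drop = FALSE]
    }
    coords[[role]] <- A
  }
  trajectory(times, coords, box)
}

#' Read GRO coordinates as a trajectory
#'
#' Reads single- or multi-frame GROMACS `.gro` files (fixed-width columns,
#' nm units, orthorhombic box line). Atom names are mapped to roles via
#' `role_map`; unmapped atoms are dropped.
#'
#' @param path File path.
#' @param role_map Named character vector mapping atom names to roles.
#' @return A [trajectory].
#' @export
read_gro <- function(path,
                     role_map = c(MG = "Mg", OW = "Ow", CL = "Cl",
                                  O1P = "OP", O2P = "OP", OP = "OP")) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); times <- numeric(); boxes <- list()
  i <- 1L
  while (i <= length(lines)) {
    title <- lines[i]
    natoms <- as.integer(trimws(lines[i + 1L]))
    if (is.na(natoms)) stop("malformed GRO atom count at line ", i + 1L)
    atom_lines <- lines[(i + 2L):(i + 1L + natoms)]
    box_line <- as.numeric(strsplit(trimws(lines[i + 2L + natoms]), "\\s+")[[1]])
    if (length(box_line) < 3L) stop("malformed GRO box line")
    if (length(box_line) > 3L && any(abs(box_line[4:length(box_line)]) > 1e-9))
      stop("triclinic GRO box not supported")
    name <- trimws(substr(atom_lines, 11, 15))
    x <- as.numeric(substr(atom_lines, 21, 28))
    y <- as.numeric(substr(atom_lines, 29, 36))
    z <- as.numeric(substr(atom_lines, 37, 44))
    t_ps <- if (grepl("t=", title))
      as.numeric(sub(".*t=\\s*([0-9.eE+-]+).*", "\\1", title)) else
      length(times)
    frames[[length(frames) + 1L]] <- data.frame(name = name, x = x, y = y, z = z)
    times <- c(times, t_ps)
    boxes[[length(boxes) + 1L]] <- box_line[1:3]
    i <- i + 3L + natoms
  }
  nf <- length(frames)
  f1 <- frames[[1]]
  roles <- role_map[f1$name]
  coords <- list()
  for (role in unique(stats::na.omit(roles))) {
    sel <- which(!is.na(roles) & roles == role)
    A <- array(NA_real_, c(nf, length(sel), 3))
    for (t in seq_len(nf))
      A[t, , ] <- as.matrix(frames[[t]][sel, c("x", "y", "z")])
    coords[[role]] <- A
  }
  if (length(coords) == 0L) stop("no atoms matched the role map")
  if (nf > 1L && any(diff(times) <= 0)) times <- seq_len(nf) - 1
  trajectory(times, coords, do.call(rbind, boxes))
}

#' Read a force-field parameter config
#'
#' Flat TOML-style config with `[species.<name>]` blocks (`charge`,
#' `sigma_nm`, `epsilon_kJmol`, optional `mass`) and `[scaling.<tag>]`
#' blocks (`lambda_sigma`, `lambda_epsilon`).
#'
#' @param path File path.
#' @return List with `species` (named list of [ion_model]) and `scalings`
#'   (named list of [scaling_factors]).
#' @export
read_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  species <- list(); scalings <- list()
  section <- NULL
  kv <- list()
  flush <- function() {
    if (is.null(section)) return()
    parts <- strsplit(section, ".", fixed = TRUE)[[1]]
    if (parts[1] == "species") {
      species[[parts[2]]] <<- ion_model(
        parts[2], as.numeric(kv$charge),
        lj_params(as.numeric(kv$sigma_nm), as.numeric(kv$epsilon_kJmol)),
        mass = if (!is.null(kv$mass)) as.numeric(kv$mass) else NA_real_)
    } else if (parts[1] == "scaling") {
      scalings[[parts[2]]] <<- scaling_factors(
        as.numeric(kv$lambda_sigma), as.numeric(kv$lambda_epsilon), parts[2])
    } else stop("unknown config section [", section, "]")
  }
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      flush()
      section <- gsub("^\\[|\\]$", "", ln)
      kv <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      p <- strsplit(ln, "=", fixed = TRUE)[[1]]
      kv[[trimws(p[1])]] <- trimws(paste(p[-1], collapse = "="))
    } else stop("cannot parse config line: ", ln)
  }
  flush()
  list(species = species, scalings = scalings)
}

#' Write a force-field parameter config
#'
#' Inverse of [read_params].
#'
#' @param path Output path.
#' @param species Named list of [ion_model] objects.
#' @param scalings Named list of [scaling_factors].
#' @export
write_params <- function(path, species, scalings = list()) {
  con <- file(path, "w"); on.exit(close(con))
  for (sp in species) {
    writeLines(sprintf("[species.%s]", sp$name), con)
    writeLines(sprintf("charge = %.8g", sp$charge), con)
    writeLines(sprintf("sigma_nm = %.8g", sp$lj$sigma), con)
    writeLines(sprintf("epsilon_kJmol = %.8g", sp$lj$epsilon), con)
    if (is.finite(sp$mass)) writeLines(sprintf("mass = %.8g", sp$mass), con)
    writeLines("", con)
  }
  for (sc in scalings) {
    writeLines(sprintf("[scaling.%s]", sc$species_tag), con)
    writeLines(sprintf("lambda_sigma = %.8g", sc$lambda_sigma), con)
    writeLines(sprintf("lambda_epsilon = %.8g", sc$lambda_epsilon), con)
    writeLines("", con)
  }
  invisible(path)
}

.atomic_number <- function(name) {
  lut <- c(Mg = 12L, Cl = 17L, O = 8L, N = 7L, C = 6L, H = 1L, P = 15L,
           Na = 11L, K = 19L, Ca = 20L)
  key <- names(lut)[match(toupper(substr(name, 1, 2)),
                          toupper(names(lut)))]
  if (is.na(key) || length(key) == 0L) {
    key <- names(lut)[match(toupper(substr(name, 1, 1)), toupper(names(lut)))]
  }
  if (length(key) == 0L || is.na(key)) 0L else lut[[key]]
}

#' Emit a GROMACS topology-include snippet
#'
#' Writes an `[ atomtypes ]` entry for the ion and one explicit
#' `[ nonbond_params ]` pair override per partner type belonging to a
#' scaled class, computed via [combine_scaled]. Water and unscaled classes
#' receive no override (the engine's standard combination rules apply).
#' Combination-rule-2 semantics (sigma/epsilon columns) are used.
#'
#' @param ion An [ion_model].
#' @param scalings List of [scaling_factors]; each `species_tag` must match
#'   at least one partner class.
#' @param partner_types Data frame with columns `type` (atom type name),
#'   `sigma` (nm), `epsilon` (kJ/mol), `class` (one of the scaling tags,
#'   `"water"`, or `"other"`).
#' @return An object of class `topology_snippet` (fields `atomtypes`,
#'   `pairs`, `text`); `format()`/`as.character()` yields the file text.
#' @export
emit_itp <- function(ion, scalings, partner_types) {
  stopifnot(inherits(ion, "ion_model"), is.data.frame(partner_types))
  .need_cols(partner_types, c("type", "sigma", "epsilon", "class"), "emit_itp")
  if (anyDuplicated(partner_types$type))
    stop("duplicate partner types: ",
         paste(unique(partner_types$type[duplicated(partner_types$type)]),
               collapse = ", "))
  if (inherits(scalings, "scaling_factors")) scalings <- list(scalings)
  tags <- vapply(scalings, function(s) s$species_tag, character(1))
  for (tag in tags)
    if (!tag %in% partner_types$class)
      stop("scaling tag '", tag, "' matches no partner class (classes: ",
           paste(unique(partner_types$class), collapse = ", "), ")")
  atomtypes <- data.frame(
    name = ion$name, at_num = .atomic_number(ion$name),
    mass = if (is.finite(ion$mass)) ion$mass else 0,
    charge = ion$charge, sigma = ion$lj$sigma, epsilon = ion$lj$epsilon,
    stringsAsFactors = FALSE)
  rows <- list()
  for (s in scalings) {
    # unit factors reduce to the engine's standard rules: no override needed
    if (s$lambda_sigma == 1 && s$lambda_epsilon == 1) next
    part <- partner_types[partner_types$class == s$species_tag, , drop = FALSE]
    for (j in seq_len(nrow(part))) {
      pij <- combine_scaled(ion$lj, lj_params(part$sigma[j], part$epsilon[j]), s)
      rows[[length(rows) + 1L]] <- data.frame(
        type_i = ion$name, type_j = part$type[j],
        sigma = pij$sigma_ij, epsilon = pij$epsilon_ij,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type_i = character(), type_j = character(),
               sigma = numeric(), epsilon = numeric())
  snip <- structure(list(atomtypes = atomtypes, pairs = pairs,
                         dialect = "gromacs"),
                    class = "topology_snippet")
  snip
}

#' @export
format.topology_snippet <- function(x, ...) {
  out <- c("[ atomtypes ]",
           "; name  at.num  mass  charge  ptype  sigma  epsilon")
  for (j in seq_len(nrow(x$atomtypes))) {
    a <- x$atomtypes[j, ]
    out <- c(out, sprintf("%-6s %4d %12.6f %12.6f  A  %.6e  %.6e",
                          a$name, a$at_num, a$mass, a$charge, a$sigma,
                          a$epsilon))
  }
  out <- c(out, "", "[ nonbond_params ]",
           "; i  j  func  sigma  epsilon")
  for (j in seq_len(nrow(x$pairs))) {
    p <- x$pairs[j, ]
    out <- c(out, sprintf("%-6s %-6s 1  %.6e  %.6e",
                          p$type_i, p$type_j, p$sigma, p$epsilon))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' @export
print.topology_snippet <- function(x, ...) {
  cat(format(x))
  invisible(x)
}

#' @export
as.character.topology_snippet <- function(x, ...) format(x)

#' Parse a GROMACS topology-include snippet
#'
#' Inverse of [emit_itp] on its own output; tolerant of comments and blank
#' lines.
#'
#' @param text Character: file text (single string or vector of lines), or
#'   a path to an existing file.
#' @return A `topology_snippet`.
#' @export
parse_itp <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  else if (length(text) == 1L)
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  section <- ""
  at <- list(); pr <- list()
  for (li in seq_along(text)) {
    ln <- trimws(sub(";.*$", "", text[li]))
    if (!nzchar(ln)) next
    if (grepl("^\\[", ln)) {
      section <- gsub("\\[|\\]|\\s", "", ln)
      next
    }
    f <- strsplit(ln, "\\s+")[[1]]
    if (section == "atomtypes") {
      if (length(f) != 7L || is.na(suppressWarnings(as.numeric(f[6]))))
        stop("malformed atomtypes record at line ", li, ": ", text[li])
      at[[length(at) + 1L]] <- data.frame(
        name = f[1], at_num = as.integer(f[2]), mass = as.numeric(f[3]),
        charge = as.numeric(f[4]), sigma = as.numeric(f[6]),
        epsilon = as.numeric(f[7]), stringsAsFactors = FALSE)
    } else if (section == "nonbond_params") {
      if (length(f) != 5L || f[3] != "1")
        stop("malformed nonbond_params record at line ", li, ": ", text[li])
      pr[[length(pr) + 1L]] <- data.frame(
        type_i = f[1], type_j = f[2], sigma = as.numeric(f[4]),
        epsilon = as.numeric(f[5]), stringsAsFactors = FALSE)
    } # other sections ignored
  }
  atomtypes <- if (length(at)) do.call(rbind, at) else
    data.frame(name = character(), at_num = integer(), mass = numeric(),
               charge = numeric(), sigma = numeric(), epsilon = numeric())
  pairs <- if (length(pr)) do.call(rbind, pr) else
    data.frame(type_i = character(), type_j = character(),
               sigma = numeric(), epsilon = numeric())
  key <- paste(pairs$type_i, pairs$type_j)
  if (anyDuplicated(key)) stop("duplicate pair overrides: ",
                               paste(key[duplicated(key)], collapse = ", "))
  structure(list(atomtypes = atomtypes, pairs = pairs, dialect = "gromacs"),
            class = "topology_snippet")
}
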