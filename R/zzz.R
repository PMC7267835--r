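.onLoad <- function(libname, pkgname) {
  # point reticulate at the environment's python before it tries to
  # provision one of its own; the scipy import itself is lazy
  if (Sys.getenv("RETICULATE_PYTHON") == "" &&
      is.null(getOption("reticulate.python"))) {
    py <- Sys.which("python3")
    if (py == "") py <- Sys.which("python")
    if (py != "") Sys.setenv(RETICULATE_PYTHON = py)
  }
  invisible()
}
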