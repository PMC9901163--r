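# Subprocess bridge to the RDKit toolkit (Python). All chemistry perception
# (SMILES parsing, ETKDG conformers, aromaticity, H-bond roles) is delegated
# to RDKit; everything downstream of the MoleculeRecord is native R.

bridge_script <- function() {
  path <- system.file("python", "ffinet_rdkit.py", package = "ffinet")
  if (!nzchar(path)) stop_config("bridge script not found; is ffinet installed?")
  path
}

python_binary <- function() {
  bin <- getOption("ffinet.python", Sys.which("python"))
  if (!nzchar(bin))
    stop_config("no `python` binary on PATH; the RDKit bridge requires one ",
                "(set options(ffinet.python = ...) to point at it)")
  bin
}

#' @noRd
rdkit_call <- function(command, payload) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)))
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- system2(python_binary(),
                    c(bridge_script(), command, shQuote(infile), shQuote(outfile)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(outfile))
    stop_config("RDKit bridge call failed (command: ", command, ")")
  resp <- jsonlite::read_json(outfile, simplifyVector = FALSE)
  if (!isTRUE(resp$bridge_ok))
    stop_config("RDKit bridge error: ", resp$error %||% "unknown")
  resp
}

#' Is the RDKit bridge usable?
#'
#' @return TRUE when a `python` with importable RDKit is reachable.
#' @export
rdkit_available <- function() {
  cached <- getOption(".ffinet_rdkit_ok")
  if (!is.null(cached)) return(cached)
  ok <- tryCatch({
    resp <- rdkit_call("validate", list(smiles = list("C")))
    isTRUE(resp$ok[[1]])
  }, error = function(e) FALSE)
  options(.ffinet_rdkit_ok = ok)
  ok
}
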