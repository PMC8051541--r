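Package: splintfab
Title: Scripted Design of 3D-Printable Lattice Splints from Limb Surface Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Turns a closed surface scan of a limb segment into a two-piece,
    watertight, 3D-printable lattice splint. The pipeline drafts an offset
    shell at the bar radius above the skin, crops it with configured cut
    planes, rebuilds it as a quasi-uniform triangle mesh, relaxes the lattice
    with a damped mass-spring system so triangle sizes equalize while nodes
    stay on the offset surface, and converts the wireframe into a printable
    solid (capsule struts, fastening blocks with through-holes, plane split
    into two pieces). Includes a parametric synthetic-limb generator so the
    whole pipeline is testable without scan data, STL/OBJ input/output, mesh
    validation, and a single-config command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
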