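Package: peppytwin
Title: Digital Twin of a Modular Articulated Tangible Peptide Interface
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pure-software digital twin of a tangible, modular and
    articulated coarse-grained peptide interface. Provides the domain
    model for the five part types (methyl, amide, alpha-carbon, C- and
    N-terminus), forward kinematics of articulated chains with
    disconnection and recursive reconnection, a small command language
    with '.pusmol' script persistence and PDB export at the physical
    model's 18.7 mm per Angstrom scale, plus discrete-time simulations
    of the device layer: 14-bit hall-effect angle sensors with magnet
    offset correction, the infrared pairing handshake between freshly
    plugged parts, and the wireless node network (static 5-ary tree and
    dynamic rerouting topologies, gateway routing, over-the-air
    firmware paging, node ID allocation).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
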