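---
title: "peppytwin: models, conventions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{peppytwin: models, conventions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peppytwin)
```

`peppytwin` is a software-only twin of a tangible molecular interface:
a coarse-grained peptide model whose printed modules carry angle
sensors, infrared pairing hardware and a wireless mesh, so that the
physical chain drives a virtual one. This vignette explains the models
the package implements, the parameters that matter, and the decisions
taken where the design was genuinely open.

## The articulated chain model

### Parts, faces, chemistry

Five part kinds exist: `METHYL`, `AMIDE`, `ALPHA_CARBON`, `C_TERM` and
`N_TERM`. Each is a rigid body defined in its own local frame by a
geometry table: atom positions (model millimetres) plus one *face* per
pluggable junction. A face carries a unit shaft axis, an anchor atom
position, half a bond length of shaft (junctions sit at bond
midpoints), a connector role (the alpha-carbon is the passive, magnet
side of every junction; all other parts hold the sensor), and the set
of allowed partner faces. The partner sets encode the chemistry rules
of the underlying coarse-grained model — methyl and the terminal caps
plug only into an alpha-carbon, an amide plugs into an alpha-carbon by
either its C or its N face — and are mirrored on both sides, which is
what makes `validate_connection()` symmetric in the choice of parent.

Face numbering is fixed and documented: alpha-carbon face 0 points to
the N-side amide (or N-terminus), face 1 to the C-side amide (or
C-terminus), face 2 to the side chain; the amide's face 0 is its C
face, face 1 its N face.

The published description of the physical interface never tabulates
its parts' internal coordinates, so `default_geometry()` is a
**synthetic reconstruction**: standard peptide bond lengths and angles
(Cα–N 1.455 Å, Cα–C 1.51 Å, peptide C–N 1.325 Å, C=O 1.23 Å,
tetrahedral alpha-carbon, planar trans amide) at the physical scale of
18.7 mm/Å. Anyone with the real part drawings can supply their own
table as a YAML file (`read_geometry()`); the shipped
`inst/extdata/default_geometry_synthetic.yaml` is labelled synthetic
for the same reason.

### Coordinates and kinematics

All geometry lives in a left-handed, Y-up frame (X right, Y up, Z
forward), with the spherical convention
$x=\rho\cos\theta\sin\phi,\; y=\rho\cos\phi,\; z=\rho\sin\theta\sin\phi$
(angles in degrees everywhere at the API surface; radians only appear
inside trigonometric calls). A scene is a forest: each sub-chain root
sits at the origin frame and every link places the child rigidly so
the two face axes are anti-parallel at the junction, leaving exactly
one rotational degree of freedom about the shaft. Joint angles are
**absolute**, matching an absolute-position rotary sensor: setting
120° then 300° equals setting 300° once.

Numerical choices: the reference placement at angle 0 uses the
minimal-angle rotation taking the child axis onto the negated parent
axis; for the degenerate anti-parallel case a deterministic
perpendicular axis is chosen, so placement is reproducible. Children
are traversed in uid order, making `world_coordinates()`
bit-reproducible. Rigid-body and anti-parallelism invariants are
asserted in the tests at 1e-9 (absolute, on millimetre-scale
coordinates).

Rotation state is stored on the child of each junction. When an
alpha-carbon is the child its stored angle still parameterises the
junction: the physical statement that an alpha-carbon "cannot rotate
on its own" is about which side holds the sensor, not about freezing
the dihedral.

### Disconnection and reconnection

`disconnect()` removes a part and its subtree, retaining a tombstone —
the pair-face records (kinds, uids, links, angles) needed to rebuild.
`reconnect()` replays that record recursively; the round trip is the
identity on scenes. Tombstones live only inside a session; the durable
record is the `.pusmol` script. Whether the physical model would allow
re-plugging a saved sub-chain onto a *different* face is unknown, so
this implementation restores the original face only.

## The command language and export

The `.pusmol` grammar is fixed by this package (the original tool's
dialect is not recoverable): lowercase verbs, whitespace-separated
tokens, one command per line, `#` comments. Sessions record every
*successful* scene-mutating command, so `save_pusmol()` /
`load_pusmol()` round-trip any scene, and `run_script()` gives the
procedural-generation path used for long chains (20-residue backbones
build routinely in the tests).

PDB was chosen as the export format because it is the field's lingua
franca for coarse-grained pseudo-atoms; records are written through
`bio3d`. Model millimetres divide by the scale (default 18.7 mm/Å,
double the original passive model's 9.35) and the left-handed frame
converts to PDB's right-handed one by negating the Z axis — chosen so
X and Y carry over unchanged. The pseudo-atom symbols Cr (methyl
radical carbon) and Ca (alpha-carbon's carbon) export as element C.
Each part is one residue (`MTH`, `AMD`, `CAL`, `CTR`, `NTR`); each
sub-chain gets a chain ID in root creation order.

## The device layer

### Angle sensor

The sensor model is a 14-bit quantizer: raw codes 0–16383 over a full
turn, corrected angle $(raw/2^{14})\cdot360-\text{offset}$ wrapped to
[0, 360). Each physical magnet is glued at an unknown orientation, so
offsets are per-board constants in a calibration table; correction
composes additively modulo 360. The inverse mapping
(`degrees_to_raw()`, used by the fixture generator) rounds to the
nearest code, bounding the round-trip error by half a quantization
step, $360/2^{15} \approx 0.011°$. Sensor polarity (increasing raw =
counter-clockwise about +Z) is a package convention; the hardware
description does not state it. Plug detection is strict:
field > 4000 dimensionless sensor units (kept as integers, not
converted to millitesla).

### Pairing handshake

Pairing is an asynchronous, timer-interrupt protocol at 1 ms per bit
(≥1000 bps, near-instant pairing), each bit split into 8 ticks of
125 µs so START/STOP symbols can be sequenced. The transmitter pin
uses inverted logic (a NOT gate drives the pull-up IR LED); the
parallel photodiodes give the receiver direct logic; the composition
delivers every level unchanged, asserted per tick in the tests.

One handshake is START + 8-bit master ID + STOP + 4 dead bits +
START + 16 reply bits (neighbor ID, check ID) + STOP = 32 bit-periods
= 32 ms, independent of the ID values. The hardware description's
prose mentions *two* dead bits while its timing formula counts four
and totals 32 bits; this package follows the formula — the totals (32
bits, 32 ms) are self-consistent only with four — and documents the
discrepancy here. Success requires the echoed check ID to equal the
master's own ID; otherwise the protocol restarts after one idle
bit-period. Sub-bit symbol patterns are a package convention (START =
4 ticks high + 4 low, STOP the inverse, data bits level-constant); the
original chronograph is an image and fixes only the framing order.
Two independent realisations exist — frame-level (`run_pairing()`) and
tick-level maton co-simulation (`run_pairing_ticks()`) — and the tests
require them to agree byte-for-byte and tick-for-tick.

### Node network

Radio nodes hold 8-bit IDs: 0 is the gateway, 255 the diffusion
(broadcast) ID, leaving 254 addressable nodes; the radio chip supports
at most six simultaneous connections, hence trees with ≤5 children per
node. The **static** topology's addressing admits $5^5 = 3125$ modules
per frequency channel (`static_capacity()` counts them by exhaustive
enumeration of the full-depth address strings — the scheme's address
space, not the sum over shorter prefixes) but strands a subtree when
its parent dies. The **dynamic** topology reroutes: on a drop, each
orphan re-attaches to the closest-to-gateway surviving node with free
capacity, ties broken by lowest ID — the re-attachment policy is not
specified by the hardware description, so this deterministic rule is a
package decision made for reproducibility. Messages follow the tree
path between the endpoints (the gateway, ID 0, owns the routing
table); broadcast reaches every live node except the sender exactly
once.

OTA firmware updates page in 16-byte blocks, burst-mode, with a
watchdog forcing a page request every 4 s of simulated time so a lost
page can delay but never brick an update; reassembly is byte-exact.
Radio physics (range, interference, amplification levels, data rates)
are outside the functional model; a per-transfer loss probability hook
exists purely for fault-injection testing.

ID allocation implements both printed strategies: `CURRENT` (methyl
1–40, amide 41–80, alpha-carbon 81–120) and `EXTENDED` (methyl 1–85,
amide 86–255, alpha-carbon 257–510 — passive alpha-carbons carry no
radio, so they may live beyond the 8-bit space). The printed extended
table assigns 85 to both the methyl and amide ranges, presumably a
printing artefact; this package gives 85 to methyl. The terminal caps,
absent from the printed table, are electronically identical to a
methyl (one sensed junction) and draw from its range.

## The fixture generators

The generators stand in for the physical interface, so every module is
testable without hardware:

- `make_backbone(n, seed)` emits a `.pusmol` script for an n-residue
  backbone (N-cap, alternating alpha-carbon/amide with methyl side
  chains, C-cap) with joint angles drawn uniformly on [0, 360) (or
  from a discrete 60/180/300° "rotamer" set). Uniform angles are the
  default because the twin is kinematic: it must represent *any* pose
  the user forces on the physical model, not only energetically
  favourable ones.
- `make_stream(scene, seed, jitter_sd_degrees)` produces timestamped
  sensor readings via the inverse quantizer, with per-board offsets
  drawn on [0, 360) and optional Gaussian placement jitter truncated
  at ±4 SD — emulating the roughly one-degree mechanical placement
  tolerance of the boards. Ground truth is returned for recovery
  checks; with 1° jitter the mean absolute recovery error follows the
  half-normal mean $\sqrt{2/\pi}\approx0.798°$, which the tests verify
  by Monte Carlo over ≥1000 readings. Readings default to 10 ms
  spacing and a field of 6000 units (plugged).
- `make_net_scenario(n_nodes, n_drops, seed)` emits timed join/drop
  event tables replayable in either topology mode.

All fixture output is a pure function of its seed.

What the generators do **not** emulate: radio loss and latency on the
sensor stream, sensor noise beyond quantization and placement jitter,
partial plugs or chattering fields around the threshold, and any
energetic preference among conformers. Passing tests therefore
demonstrate protocol and kinematic correctness, not robustness to
every artefact of a physical deployment.

## Problem sizes

The test-suite defaults are desk-scale and chosen as comfortably
representative: backbones of 1–20 residues, sensor streams of ~10^3–10^4
readings, networks up to the full 254-node ID space, firmware images up
to 1 KiB, and exhaustive enumerations where the space is small (all 256
byte frames, all 8 check-ID bit flips, the 3125-address static tree).

## Known limitations

- Kinematics only: no physics engine, no collision detection, no
  magnetic-detent potential at the plinths, no rendering.
- The geometry defaults are reconstructions, not measurements of the
  printed parts; quantitative coordinate comparisons against the real
  device require its geometry table.
- No compatibility is claimed with the original simulator's `.pusmol`
  dialect.
- The global orientation of the interface is unmeasured by the real
  hardware and likewise unmodelled here; only relative joint angles
  exist.
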