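# Default scalp montage for the 17-channel vigilance setup.
# Edges encode physical adjacency on the scalp: chains along each temporal
# strip and grid neighbours within the posterior block. CPZ is the reference
# electrode and is absent. Edit and pass to load_montage() to change the
# fixed spatial-relationship graph.
channel_names:
  - FT7
  - FT8
  - T7
  - T8
  - TP7
  - TP8
  - CP1
  - CP2
  - P1
  - PZ
  - P2
  - PO3
  - POZ
  - PO4
  - O1
  - OZ
  - O2
edges:
  - [FT7, T7]
  - [T7, TP7]
  - [FT8, T8]
  - [T8, TP8]
  - [CP1, P1]
  - [P1, PZ]
  - [PZ, P2]
  - [P2, CP2]
  - [P1, PO3]
  - [PZ, POZ]
  - [P2, PO4]
  - [PO3, POZ]
  - [POZ, PO4]
  - [PO3, O1]
  - [POZ, OZ]
  - [PO4, O2]
  - [O1, OZ]
  - [OZ, O2]
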