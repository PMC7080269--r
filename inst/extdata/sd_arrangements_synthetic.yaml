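# Synthetic source-detector pair arrangements over the 16 prefrontal fNIRS
# channels. Each source-detector pair added to the lattice contributes the
# channels of its adjacent source-detector links; two lattice pairs induce
# four channels (e.g. the left-DLPFC block 5/10/11/16 and the right-DLPFC
# block 1/6/7/12). These are plausible stand-ins for a real optode-geometry
# table, not recorded hardware coordinates.
arrangements:
  - name: left-1pair
    n_pairs: 1
    channels: [16]
  - name: right-1pair
    n_pairs: 1
    channels: [12]
  - name: left-dlpfc-2pair
    n_pairs: 2
    channels: [5, 10, 11, 16]
  - name: right-dlpfc-2pair
    n_pairs: 2
    channels: [1, 6, 7, 12]
  - name: medial-2pair
    n_pairs: 2
    channels: [3, 8, 9, 14]
  - name: left-3pair
    n_pairs: 3
    channels: [4, 5, 9, 10, 11, 15, 16]
  - name: right-3pair
    n_pairs: 3
    channels: [1, 2, 6, 7, 8, 12, 13]
  - name: lateral-4pair
    n_pairs: 4
    channels: [1, 2, 4, 5, 6, 7, 10, 11, 12, 15, 16, 9]
  - name: broad-5pair
    n_pairs: 5
    channels: [1, 2, 3, 4, 5, 6, 7, 9, 10, 11, 12, 14, 15, 16]
  - name: full-6pair
    n_pairs: 6
    channels: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16]
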