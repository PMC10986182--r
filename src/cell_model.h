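#ifndef FIBROSIM_CELL_MODEL_H
#define FIBROSIM_CELL_MODEL_H

// State layout for the ventricular myocyte model (ten Tusscher 2006 with an
// added late sodium current). All voltages in mV, time in ms, currents in
// pA/pF, concentrations in mM.
#define FS_NSTATE 21
enum fs_state_idx {
  FS_V = 0, FS_M, FS_H, FS_J, FS_XR1, FS_XR2, FS_XS, FS_R, FS_S,
  FS_D, FS_F, FS_F2, FS_FCASS, FS_RR, FS_CAI, FS_CASR, FS_CASS,
  FS_NAI, FS_KI, FS_ML, FS_HL
};

// Ionic scale factors (all 1.0 = healthy). Order is part of the R contract.
#define FS_NSCALE 8
enum fs_scale_idx {
  FS_S_NAL = 0, FS_S_CAL, FS_S_KR, FS_S_KS, FS_S_TO, FS_S_K1,
  FS_S_NCX, FS_S_SERCA
};

// Cell variants (transmural types of the ten Tusscher 2006 model).
#define FS_EPI 0
#define FS_ENDO 1
#define FS_MCELL 2

// Voltage-gated (Rush-Larsen) gates, in LUT order.
#define FS_NGATE 13

#endif
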