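# Illustrative (synthetic) reference geometry for the underactuated finger
# linkage. The physical hand's link dimensions are unpublished; these were
# constructed so that the full 10 mm actuator stroke flexes the proximal
# joint through ~84.5 degrees. Matches reference_geometry() in the package.
lengths_mm:
  r1: 22.036264087073505
  r2: 62.33318146636274548
  r3: 40.0
  r4: 28.316366059705615
  r5: 25.0
  r6: 36.37382713681481050
  r7: 19.477148687466979
  r8: 9.2117981053888798
delta_deg: 17.566473064944148
beta_deg: -55.709370067343116
theta7_deg: -82.163704996928573
crank:
  radius_mm: 10.467700406920363
  s_ref_mm: 0.0
  theta_ref_deg: 198.78354310523719
driven: theta2
proximal_limit_deg: 84.5
distal_limit_deg: 135.0
guess_deg:
  theta1: 77.986312202410772
  theta2: 198.78354310523719
  theta3: 49.175758130149916
  theta4: 64.01457635798937
  theta5: 55.650541178801696
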