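data_vaterite_p6522_synthetic
_cell_length_a    7.200000
_cell_length_b    7.200000
_cell_length_c    26.163211
_cell_angle_alpha 90.000000
_cell_angle_beta  90.000000
_cell_angle_gamma 120.000000
_symmetry_space_group_name_H-M 'P6_522'
loop_
_symmetry_equiv_pos_as_xyz
'x,y,z'
'x-y,x,z+5/6'
'-y,x-y,z+2/3'
'-x,-y,z+1/2'
'-x+y,-x,z+1/3'
'y,-x+y,z+1/6'
'-y,-x,-z+1/6'
'-x,-x+y,-z+1/3'
'-x+y,y,-z+1/2'
'y,x,-z+2/3'
'x,x-y,-z+5/6'
'x-y,-y,-z'
loop_
_atom_site_label
_atom_site_type_symbol
_atom_site_fract_x
_atom_site_fract_y
_atom_site_fract_z
_atom_site_occupancy
_atom_site_B_iso_or_equiv
Ca1 Ca 0.332000000 0.072000000 0.044000000 1.000000 0.000000
Ca2 Ca 0.413000000 0.000000000 0.000000000 1.000000 0.000000
C3 C 0.345000000 0.410000000 0.127000000 1.000000 0.000000
C4 C 0.280000000 0.560000000 0.250000000 1.000000 0.000000
O5 O 0.266000000 0.468000000 0.083000000 1.000000 0.000000
O6 O 0.254000000 0.270000000 0.152000000 1.000000 0.000000
O7 O 0.478000000 0.482000000 0.140000000 1.000000 0.000000
O8 O 0.090000000 0.380000000 0.205000000 1.000000 0.000000
O9 O 0.175000000 0.175000000 0.333333333 1.000000 0.000000
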