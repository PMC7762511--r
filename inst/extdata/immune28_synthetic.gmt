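Activated_CD4_T_cell	synthetic placeholder signature	IMM01G01	IMM01G02	IMM01G03	IMM01G04	IMM01G05	IMM01G06	IMM01G07	IMM01G08	IMM01G09	IMM01G10	IMM01G11	IMM01G12	IMM01G13	IMM01G14	IMM01G15
Activated_CD8_T_cell	synthetic placeholder signature	IMM02G01	IMM02G02	IMM02G03	IMM02G04	IMM02G05	IMM02G06	IMM02G07	IMM02G08	IMM02G09	IMM02G10	IMM02G11	IMM02G12	IMM02G13	IMM02G14	IMM02G15
Central_memory_CD4_T_cell	synthetic placeholder signature	IMM03G01	IMM03G02	IMM03G03	IMM03G04	IMM03G05	IMM03G06	IMM03G07	IMM03G08	IMM03G09	IMM03G10	IMM03G11	IMM03G12	IMM03G13	IMM03G14	IMM03G15
Central_memory_CD8_T_cell	synthetic placeholder signature	IMM04G01	IMM04G02	IMM04G03	IMM04G04	IMM04G05	IMM04G06	IMM04G07	IMM04G08	IMM04G09	IMM04G10	IMM04G11	IMM04G12	IMM04G13	IMM04G14	IMM04G15
Effector_memory_CD4_T_cell	synthetic placeholder signature	IMM05G01	IMM05G02	IMM05G03	IMM05G04	IMM05G05	IMM05G06	IMM05G07	IMM05G08	IMM05G09	IMM05G10	IMM05G11	IMM05G12	IMM05G13	IMM05G14	IMM05G15
Effector_memory_CD8_T_cell	synthetic placeholder signature	IMM06G01	IMM06G02	IMM06G03	IMM06G04	IMM06G05	IMM06G06	IMM06G07	IMM06G08	IMM06G09	IMM06G10	IMM06G11	IMM06G12	IMM06G13	IMM06G14	IMM06G15
Type_1_T_helper_cell	synthetic placeholder signature	IMM07G01	IMM07G02	IMM07G03	IMM07G04	IMM07G05	IMM07G06	IMM07G07	IMM07G08	IMM07G09	IMM07G10	IMM07G11	IMM07G12	IMM07G13	IMM07G14	IMM07G15
Type_17_T_helper_cell	synthetic placeholder signature	IMM08G01	IMM08G02	IMM08G03	IMM08G04	IMM08G05	IMM08G06	IMM08G07	IMM08G08	IMM08G09	IMM08G10	IMM08G11	IMM08G12	IMM08G13	IMM08G14	IMM08G15
Activated_dendritic_cell	synthetic placeholder signature	IMM09G01	IMM09G02	IMM09G03	IMM09G04	IMM09G05	IMM09G06	IMM09G07	IMM09G08	IMM09G09	IMM09G10	IMM09G11	IMM09G12	IMM09G13	IMM09G14	IMM09G15
CD56bright_natural_killer_cell	synthetic placeholder signature	IMM10G01	IMM10G02	IMM10G03	IMM10G04	IMM10G05	IMM10G06	IMM10G07	IMM10G08	IMM10G09	IMM10G10	IMM10G11	IMM10G12	IMM10G13	IMM10G14	IMM10G15
Natural_killer_cell	synthetic placeholder signature	IMM11G01	IMM11G02	IMM11G03	IMM11G04	IMM11G05	IMM11G06	IMM11G07	IMM11G08	IMM11G09	IMM11G10	IMM11G11	IMM11G12	IMM11G13	IMM11G14	IMM11G15
Natural_killer_T_cell	synthetic placeholder signature	IMM12G01	IMM12G02	IMM12G03	IMM12G04	IMM12G05	IMM12G06	IMM12G07	IMM12G08	IMM12G09	IMM12G10	IMM12G11	IMM12G12	IMM12G13	IMM12G14	IMM12G15
Regulatory_T_cell	synthetic placeholder signature	IMM13G01	IMM13G02	IMM13G03	IMM13G04	IMM13G05	IMM13G06	IMM13G07	IMM13G08	IMM13G09	IMM13G10	IMM13G11	IMM13G12	IMM13G13	IMM13G14	IMM13G15
Type_2_T_helper_cell	synthetic placeholder signature	IMM14G01	IMM14G02	IMM14G03	IMM14G04	IMM14G05	IMM14G06	IMM14G07	IMM14G08	IMM14G09	IMM14G10	IMM14G11	IMM14G12	IMM14G13	IMM14G14	IMM14G15
CD56dim_natural_killer_cell	synthetic placeholder signature	IMM15G01	IMM15G02	IMM15G03	IMM15G04	IMM15G05	IMM15G06	IMM15G07	IMM15G08	IMM15G09	IMM15G10	IMM15G11	IMM15G12	IMM15G13	IMM15G14	IMM15G15
Immature_dendritic_cell	synthetic placeholder signature	IMM16G01	IMM16G02	IMM16G03	IMM16G04	IMM16G05	IMM16G06	IMM16G07	IMM16G08	IMM16G09	IMM16G10	IMM16G11	IMM16G12	IMM16G13	IMM16G14	IMM16G15
Macrophage	synthetic placeholder signature	IMM17G01	IMM17G02	IMM17G03	IMM17G04	IMM17G05	IMM17G06	IMM17G07	IMM17G08	IMM17G09	IMM17G10	IMM17G11	IMM17G12	IMM17G13	IMM17G14	IMM17G15
MDSC	synthetic placeholder signature	IMM18G01	IMM18G02	IMM18G03	IMM18G04	IMM18G05	IMM18G06	IMM18G07	IMM18G08	IMM18G09	IMM18G10	IMM18G11	IMM18G12	IMM18G13	IMM18G14	IMM18G15
Neutrophil	synthetic placeholder signature	IMM19G01	IMM19G02	IMM19G03	IMM19G04	IMM19G05	IMM19G06	IMM19G07	IMM19G08	IMM19G09	IMM19G10	IMM19G11	IMM19G12	IMM19G13	IMM19G14	IMM19G15
Plasmacytoid_dendritic_cell	synthetic placeholder signature	IMM20G01	IMM20G02	IMM20G03	IMM20G04	IMM20G05	IMM20G06	IMM20G07	IMM20G08	IMM20G09	IMM20G10	IMM20G11	IMM20G12	IMM20G13	IMM20G14	IMM20G15
Activated_B_cell	synthetic placeholder signature	IMM21G01	IMM21G02	IMM21G03	IMM21G04	IMM21G05	IMM21G06	IMM21G07	IMM21G08	IMM21G09	IMM21G10	IMM21G11	IMM21G12	IMM21G13	IMM21G14	IMM21G15
Gamma_delta_T_cell	synthetic placeholder signature	IMM22G01	IMM22G02	IMM22G03	IMM22G04	IMM22G05	IMM22G06	IMM22G07	IMM22G08	IMM22G09	IMM22G10	IMM22G11	IMM22G12	IMM22G13	IMM22G14	IMM22G15
Immature_B_cell	synthetic placeholder signature	IMM23G01	IMM23G02	IMM23G03	IMM23G04	IMM23G05	IMM23G06	IMM23G07	IMM23G08	IMM23G09	IMM23G10	IMM23G11	IMM23G12	IMM23G13	IMM23G14	IMM23G15
Memory_B_cell	synthetic placeholder signature	IMM24G01	IMM24G02	IMM24G03	IMM24G04	IMM24G05	IMM24G06	IMM24G07	IMM24G08	IMM24G09	IMM24G10	IMM24G11	IMM24G12	IMM24G13	IMM24G14	IMM24G15
T_follicular_helper_cell	synthetic placeholder signature	IMM25G01	IMM25G02	IMM25G03	IMM25G04	IMM25G05	IMM25G06	IMM25G07	IMM25G08	IMM25G09	IMM25G10	IMM25G11	IMM25G12	IMM25G13	IMM25G14	IMM25G15
Eosinophil	synthetic placeholder signature	IMM26G01	IMM26G02	IMM26G03	IMM26G04	IMM26G05	IMM26G06	IMM26G07	IMM26G08	IMM26G09	IMM26G10	IMM26G11	IMM26G12	IMM26G13	IMM26G14	IMM26G15
Mast_cell	synthetic placeholder signature	IMM27G01	IMM27G02	IMM27G03	IMM27G04	IMM27G05	IMM27G06	IMM27G07	IMM27G08	IMM27G09	IMM27G10	IMM27G11	IMM27G12	IMM27G13	IMM27G14	IMM27G15
Monocyte	synthetic placeholder signature	IMM28G01	IMM28G02	IMM28G03	IMM28G04	IMM28G05	IMM28G06	IMM28G07	IMM28G08	IMM28G09	IMM28G10	IMM28G11	IMM28G12	IMM28G13	IMM28G14	IMM28G15
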