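"id","x","y","es_class","state_code","dataset"
"fp001",15,-15,"Sandy",4,"SB"
"fp002",45,-15,"Sandy",6,"DG"
"fp003",75,-15,"Sandy",4,"TR"
"fp004",105,-15,"Sandy",2,"MV"
"fp005",135,-15,"Sandy",4,"SB"
"fp006",165,-15,"Sandy",2,"DG"
"fp007",195,-15,"Sandy",1,"TR"
"fp008",225,-15,"Sandy",6,"MV"
"fp009",255,-15,"Sandy",4,"SB"
"fp010",285,-15,"Sandy",4,"DG"
"fp011",315,-15,"Sandy",4,"TR"
"fp012",345,-15,"Sandy",4,"MV"
"fp013",375,-15,"Sandy",4,"SB"
"fp014",405,-15,"Sandy",1,"DG"
"fp015",435,-15,"Sandy",2,"TR"
"fp016",465,-15,"Sandy",4,"MV"
"fp017",15,-45,"Sandy",4,"SB"
"fp018",45,-45,"Sandy",6,"DG"
"fp019",75,-45,"Sandy",4,"TR"
"fp020",105,-45,"Sandy",4,"MV"
"fp021",135,-45,"Sandy",6,"SB"
"fp022",165,-45,"Sandy",1,"DG"
"fp023",195,-45,"Sandy",4,"TR"
"fp024",225,-45,"Sandy",4,"MV"
"fp025",255,-45,"Sandy",2,"SB"
"fp026",285,-45,"Sandy",2,"DG"
"fp027",315,-45,"Sandy",7,"TR"
"fp028",345,-45,"Sandy",2,"MV"
"fp029",375,-45,"Sandy",4,"SB"
"fp030",405,-45,"Sandy",6,"DG"
"fp031",435,-45,"Sandy",2,"TR"
"fp032",465,-45,"Sandy",2,"MV"
"fp033",15,-75,"Sandy",4,"SB"
"fp034",45,-75,"Sandy",4,"DG"
"fp035",75,-75,"Sandy",4,"TR"
"fp036",105,-75,"Sandy",6,"MV"
"fp037",135,-75,"Sandy",7,"SB"
"fp038",165,-75,"Sandy",4,"DG"
"fp039",195,-75,"Sandy",7,"TR"
"fp040",225,-75,"Sandy",6,"MV"
"fp041",255,-75,"Sandy",4,"SB"
"fp042",285,-75,"Sandy",4,"DG"
"fp043",315,-75,"Sandy",2,"TR"
"fp044",345,-75,"Sandy",7,"MV"
"fp045",375,-75,"Sandy",4,"SB"
"fp046",405,-75,"Sandy",2,"DG"
"fp047",435,-75,"Sandy",2,"TR"
"fp048",465,-75,"Sandy",4,"MV"
"fp049",15,-105,"Sandy",7,"SB"
"fp050",45,-105,"Sandy",6,"DG"
"fp051",75,-105,"Sandy",4,"TR"
"fp052",105,-105,"Sandy",4,"MV"
"fp053",135,-105,"Sandy",4,"SB"
"fp054",165,-105,"Sandy",7,"DG"
"fp055",195,-105,"Sandy",4,"TR"
"fp056",225,-105,"Sandy",4,"MV"
"fp057",255,-105,"Sandy",4,"SB"
"fp058",285,-105,"Sandy",4,"DG"
"fp059",315,-105,"Sandy",4,"TR"
"fp060",345,-105,"Sandy",4,"MV"
"fp061",375,-105,"Sandy",4,"SB"
"fp062",405,-105,"Sandy",4,"DG"
"fp063",435,-105,"Sandy",2,"TR"
"fp064",465,-105,"Sandy",4,"MV"
"fp065",15,-135,"Sandy",6,"SB"
"fp066",45,-135,"Sandy",2,"DG"
"fp067",75,-135,"Sandy",2,"TR"
"fp068",105,-135,"Sandy",4,"MV"
"fp069",135,-135,"Sandy",6,"SB"
"fp070",165,-135,"Sandy",4,"DG"
"fp071",195,-135,"Sandy",4,"TR"
"fp072",225,-135,"Sandy",4,"MV"
"fp073",255,-135,"Sandy",4,"SB"
"fp074",285,-135,"Sandy",6,"DG"
"fp075",315,-135,"Sandy",4,"TR"
"fp076",345,-135,"Sandy",6,"MV"
"fp077",375,-135,"Sandy",4,"SB"
"fp078",405,-135,"Sandy",4,"DG"
"fp079",435,-135,"Sandy",4,"TR"
"fp080",465,-135,"Sandy",4,"MV"
"fp081",15,-165,"Sandy",6,"SB"
"fp082",45,-165,"Sandy",4,"DG"
"fp083",75,-165,"Sandy",7,"TR"
"fp084",105,-165,"Sandy",4,"MV"
"fp085",135,-165,"Sandy",4,"SB"
"fp086",165,-165,"Sandy",6,"DG"
"fp087",195,-165,"Shallow sandy",1,"TR"
"fp088",225,-165,"Shallow sandy",1,"MV"
"fp089",255,-165,"Shallow sandy",4,"SB"
"fp090",285,-165,"Shallow sandy",6,"DG"
"fp091",315,-165,"Shallow sandy",4,"TR"
"fp092",345,-165,"Shallow sandy",1,"MV"
"fp093",375,-165,"Shallow sandy",4,"SB"
"fp094",405,-165,"Shallow sandy",4,"DG"
"fp095",435,-165,"Shallow sandy",7,"TR"
"fp096",465,-165,"Shallow sandy",4,"MV"
"fp097",15,-195,"Shallow sandy",2,"SB"
"fp098",45,-195,"Shallow sandy",7,"DG"
"fp099",75,-195,"Shallow sandy",6,"TR"
"fp100",105,-195,"Shallow sandy",2,"MV"
"fp101",135,-195,"Shallow sandy",6,"SB"
"fp102",165,-195,"Shallow sandy",4,"DG"
"fp103",195,-195,"Deep sand",6,"TR"
"fp104",225,-195,"Deep sand",5,"MV"
"fp105",255,-195,"Deep sand",3,"SB"
"fp106",285,-195,"Deep sand",6,"DG"
"fp107",315,-195,"Deep sand",6,"TR"
"fp108",345,-195,"Deep sand",6,"MV"
"fp109",375,-195,"Deep sand",6,"SB"
"fp110",405,-195,"Deep sand",5,"DG"
"fp111",435,-195,"Deep sand",3,"TR"
"fp112",465,-195,"Deep sand",3,"MV"
"fp113",15,-225,"Deep sand",6,"SB"
"fp114",45,-225,"Deep sand",3,"DG"
"fp115",75,-225,"Deep sand",3,"TR"
"fp116",105,-225,"Deep sand",5,"MV"
"fp117",135,-225,"Deep sand",6,"SB"
"fp118",165,-225,"Deep sand",5,"DG"
"fp119",195,-225,"Deep sand",5,"TR"
"fp120",225,-225,"Deep sand",5,"MV"
"fp121",255,-225,"Deep sand",3,"SB"
"fp122",285,-225,"Deep sand",6,"DG"
"fp123",315,-225,"Deep sand",6,"TR"
"fp124",345,-225,"Deep sand",3,"MV"
"fp125",375,-225,"Deep sand",5,"SB"
"fp126",405,-225,"Deep sand",5,"DG"
"fp127",435,-225,"Deep sand",5,"TR"
"fp128",465,-225,"Deep sand",6,"MV"
"fp129",15,-255,"Deep sand",5,"SB"
"fp130",45,-255,"Deep sand",6,"DG"
"fp131",75,-255,"Deep sand",3,"TR"
"fp132",105,-255,"Deep sand",6,"MV"
"fp133",135,-255,"Deep sand",6,"SB"
"fp134",165,-255,"Deep sand",5,"DG"
"fp135",195,-255,"Loamy",1,"TR"
"fp136",225,-255,"Loamy",6,"MV"
"fp137",255,-255,"Loamy",4,"SB"
"fp138",285,-255,"Loamy",4,"DG"
"fp139",315,-255,"Loamy",2,"TR"
"fp140",345,-255,"Loamy",4,"MV"
"fp141",375,-255,"Loamy",6,"SB"
"fp142",405,-255,"Loamy",6,"DG"
"fp143",435,-255,"Loamy",7,"TR"
"fp144",465,-255,"Loamy",1,"MV"
"fp145",15,-285,"Loamy",4,"SB"
"fp146",45,-285,"Loamy",4,"DG"
"fp147",75,-285,"Loamy",4,"TR"
"fp148",105,-285,"Loamy",4,"MV"
"fp149",135,-285,"Loamy",2,"SB"
"fp150",165,-285,"Loamy",4,"DG"
"fp151",195,-285,"Loamy",4,"TR"
"fp152",225,-285,"Loamy",4,"MV"
"fp153",255,-285,"Loamy",4,"SB"
"fp154",285,-285,"Loamy",6,"DG"
"fp155",315,-285,"Loamy",4,"TR"
"fp156",345,-285,"Loamy",1,"MV"
"fp157",375,-285,"Loamy",2,"SB"
"fp158",405,-285,"Loamy",4,"DG"
"fp159",435,-285,"Loamy",1,"TR"
"fp160",465,-285,"Loamy",1,"MV"
"fp161",15,-315,"Loamy",6,"SB"
"fp162",45,-315,"Loamy",4,"DG"
"fp163",75,-315,"Loamy",4,"TR"
"fp164",105,-315,"Loamy",1,"MV"
"fp165",135,-315,"Loamy",4,"SB"
"fp166",165,-315,"Loamy",6,"DG"
"fp167",195,-315,"Loamy",6,"TR"
"fp168",225,-315,"Loamy",4,"MV"
"fp169",255,-315,"Loamy",2,"SB"
"fp170",285,-315,"Loamy",2,"DG"
"fp171",315,-315,"Loamy",1,"TR"
"fp172",345,-315,"Clayey",1,"MV"
"fp173",375,-315,"Clayey",4,"SB"
"fp174",405,-315,"Clayey",4,"DG"
"fp175",435,-315,"Clayey",4,"TR"
"fp176",465,-315,"Clayey",4,"MV"
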