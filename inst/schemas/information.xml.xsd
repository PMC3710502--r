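<?xml version="1.0" encoding="UTF-8"?>
<!-- information layer file, XML dialect -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">
  <xs:element name="information">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="set" maxOccurs="unbounded">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="name" type="xs:string" minOccurs="0"/>
              <xs:element name="numClass" type="xs:positiveInteger"/>
              <xs:element name="labels" minOccurs="0">
                <xs:complexType>
                  <xs:sequence>
                    <!-- one label per class: count must equal numClass -->
                    <xs:element name="label" type="xs:string" maxOccurs="unbounded"/>
                  </xs:sequence>
                </xs:complexType>
              </xs:element>
              <xs:element name="values">
                <xs:complexType>
                  <xs:sequence>
                    <!-- same order and length as the dataset's points -->
                    <xs:element name="value" type="xs:integer" maxOccurs="unbounded"/>
                  </xs:sequence>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
    </xs:complexType>
  </xs:element>
</xs:schema>
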